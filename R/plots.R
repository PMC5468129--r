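# Figures: per-line male vs female posterior mean survival with posterior
# clouds, and mean +/- 95% CI panels per regime x sex. Deterministic given
# the draws (cloud thinning is systematic, not random).

#' Per-line posterior survival draws by sex
#'
#' For each replicate line, combines the fixed-effect draws for the line's
#' regime (at a chosen cue level) with the line's random-intercept draws to
#' give draw-wise mean survival for each sex; vial effects are at their
#' population mean (0).
#'
#' @param fit a `posterior_draws` from [fit_mcmc()].
#' @param records the fitted [vial_table()] (for the line -> regime map).
#' @param cue cue level at which to evaluate (`"none"` or `"cold_shock"`).
#' @return data.frame: `draw`, `line_id`, `regime`, one column per sex.
#' @export
line_survival_draws <- function(fit, records, cue = "none") {
  stopifnot(inherits(fit, "posterior_draws"))
  vs <- vial_starts(as.data.frame(records))
  line_map <- unique(vs[, c("line_id", "regime")])
  flat <- apply(fit$draws, 3, as.vector)  # (iter*chains) x params

  sexes <- intersect(c("F", "M"), unique(vs$sex))
  out <- list()
  for (i in seq_len(nrow(line_map))) {
    lid <- line_map$line_id[i]
    u <- flat[, paste0("u_line:", lid)]
    cells <- data.frame(regime = line_map$regime[i], sex = sexes, cue = cue,
                        starv = vs$starv[1], stringsAsFactors = FALSE)
    dm <- build_design_matrix(cells, fit$spec, age_center = fit$age_center)
    mu <- flat[, fit$term_names, drop = FALSE] %*% t(dm$X)
    df <- data.frame(draw = seq_len(nrow(flat)), line_id = lid,
                     regime = line_map$regime[i], stringsAsFactors = FALSE)
    for (j in seq_along(sexes)) df[[sexes[j]]] <- mu[, j] + u
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Plot per-line male versus female posterior mean survival
#'
#' Scatter of posterior-mean survival per replicate line (male against
#' female), colour-coded by selection regime, over a thinned cloud of joint
#' posterior draws; plus a mean and 95%-CI panel per regime x sex. Both
#' panels are deterministic functions of the draws.
#'
#' @param draws_by_line output of [line_survival_draws()].
#' @param cloud_points approximate number of cloud points to keep per line
#'   (thinned systematically).
#' @return named list of ggplot objects: `scatter`, `intervals`.
#' @export
plot_survival_summaries <- function(draws_by_line, cloud_points = 200L) {
  sexes <- intersect(c("F", "M"), names(draws_by_line))
  if (length(sexes) < 2L) stop("need posterior draws for both sexes")
  n_draws <- max(draws_by_line$draw)
  step <- max(1L, floor(n_draws / cloud_points))
  cloud <- draws_by_line[draws_by_line$draw %% step == 0L, , drop = FALSE]

  agg <- stats::aggregate(draws_by_line[, sexes],
                          by = draws_by_line[, c("line_id", "regime")], mean)

  scatter <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$F, y = .data$M)) +
    ggplot2::geom_point(data = cloud, colour = "grey80", size = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), size = 2.5) +
    ggplot2::labs(x = "female mean survival (h)", y = "male mean survival (h)",
                  colour = "regime") +
    ggplot2::theme_minimal()

  long <- do.call(rbind, lapply(sexes, function(sx) {
    data.frame(regime = draws_by_line$regime, sex = sx,
               value = draws_by_line[[sx]], stringsAsFactors = FALSE)
  }))
  ci <- do.call(rbind, lapply(split(long, list(long$regime, long$sex)),
    function(g) data.frame(
      regime = g$regime[1], sex = g$sex[1], mean = mean(g$value),
      lo = stats::quantile(g$value, 0.025, names = FALSE),
      hi = stats::quantile(g$value, 0.975, names = FALSE),
      stringsAsFactors = FALSE
    )))
  intervals <- ggplot2::ggplot(
    ci, ggplot2::aes(x = .data$regime, y = .data$mean, colour = .data$regime,
                     shape = .data$sex)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "selection regime", y = "mean survival (h)") +
    ggplot2::theme_minimal()

  list(scatter = scatter, intervals = intervals)
}
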