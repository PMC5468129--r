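# Synthetic-experiment generators. Each simulator is fully reproducible from
# its seed and returns both the dataset and the generating truth, so every
# estimation stage can be validated by parameter recovery at desk scale.

#' Parameters for a simulated interval-censored survival experiment
#'
#' The generating model for each individual's latent event time is
#' `T = X beta + age_slope * (age - age_center) + u_line + u_vial + eps`,
#' with independent zero-mean normal line, vial and residual terms. Latent
#' times are observed only as per-vial counts binned into the vial's
#' inspection schedule; times beyond the assay end are right censored (times
#' at or below the first inspection, including negative ones, fall in the
#' first interval).
#'
#' @param beta named coefficient vector in hours; names must resolve on the
#'   design built from `terms` (e.g. `Intercept`, `SexM`, `SelU`, `SelC`,
#'   `CueCs`, `SelC:CueCs`).
#' @param terms fixed-effect terms defining the generating design.
#' @param sigma_resid,sigma_line,sigma_vial SDs (hours) of the individual
#'   residual, replicate-line and vial random effects.
#' @param n_lines_per_regime replicate lines per selection regime.
#' @param vials_per_cell vials per replicate line within each treatment cell.
#' @param flies_per_vial integer range `c(min, max)`; each vial's count is
#'   drawn uniformly from it.
#' @param schedule list of [schedule_spec()]s named by sex (`F`, `M`, and/or
#'   `pooled` for sex-free designs): sex-specific assay ends encode the longer
#'   female assays needed to reach comparable mortality.
#' @param age_range hours; adult age at clock start is drawn uniformly from
#'   this range per vial, and centered at its midpoint in the generator.
#' @param age_slope hours of latent-time shift per hour of (centered) age.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   datasets.
#' @return object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(beta,
                                terms = c("Sex", "Sel", "Cue", "Sel:Cue"),
                                sigma_resid = 20, sigma_line = 3, sigma_vial = 5,
                                n_lines_per_regime = 6,
                                vials_per_cell = 6,
                                flies_per_vial = c(17, 22),
                                schedule = list(
                                  F = schedule_spec(4, 12, 96),
                                  M = schedule_spec(4, 12, 72)
                                ),
                                age_range = c(84, 108),
                                age_slope = 0,
                                seed = 1L) {
  stopifnot(sigma_resid >= 0, sigma_line >= 0, sigma_vial >= 0,
            vials_per_cell >= 1, n_lines_per_regime >= 1)
  flies_per_vial <- as.integer(round(flies_per_vial))
  if (length(flies_per_vial) == 1L) flies_per_vial <- rep(flies_per_vial, 2L)
  if (flies_per_vial[1] < 1L || flies_per_vial[2] > 50L ||
      flies_per_vial[1] > flies_per_vial[2]) {
    stop("flies_per_vial must be an increasing integer range within [1, 50]")
  }
  structure(list(beta = beta, terms = terms, sigma_resid = sigma_resid,
                 sigma_line = sigma_line, sigma_vial = sigma_vial,
                 n_lines_per_regime = n_lines_per_regime,
                 vials_per_cell = vials_per_cell,
                 flies_per_vial = flies_per_vial, schedule = schedule,
                 age_range = age_range, age_slope = age_slope,
                 seed = as.integer(seed)),
            class = "survival_sim_params")
}

#' Default generating configuration at the starvation-assay scale
#'
#' Fixed effects equal the published point estimates for starvation survival
#' in hours (intercept 104.64 for regime-R females without cold shock; SexM
#' -25.80, SelU -3.89, SelC -17.92, CueCs -7.56, SelC:CueCs 3.58), and the
#' vial structure matches the assay scale: 3 regimes x 6 replicate lines x
#' 2 sexes x 2 cue levels x 6 vials = 432 vials of 17-22 flies (~8500
#' individuals, close to the experiment's 220 female + 215 male vials
#' averaging 19.8 and 18.2 flies). Assay ends (96 h females, 72 h males, with
#' 4-h daytime checks and a 12-h overnight gap) give roughly 50% mortality by
#' the end under these coefficients. Variance components (residual 20 h, line
#' 3 h, vial 5 h) are generator settings chosen to make the random effects
#' detectable, not published values.
#'
#' @param seed integer seed.
#' @return a [survival_sim_params()].
#' @export
paperlike_default_params <- function(seed = 1L) {
  survival_sim_params(
    beta = c(Intercept = 104.64, SexM = -25.80, SelU = -3.89, SelC = -17.92,
             CueCs = -7.56, `SelC:CueCs` = 3.58),
    seed = seed
  )
}

#' Default generating configuration at the egg-to-adult developmental scale
#'
#' Fixed effects equal the published developmental-time estimates in hours
#' (intercept 235.12; SelU -2.43, SelC -0.80, StarvS 4.86, SelU:StarvS 1.35,
#' SelC:StarvS 3.83), sexes pooled; 18 lines x 2 starv x 8 vials = 288 vials
#' of 5-10 eggs (~2200 individuals, matching the assay's 295 vials averaging
#' 7.6).
#'
#' @param seed integer seed.
#' @param vials_per_cell vials per line within each starvation cell.
#' @return a [survival_sim_params()].
#' @export
paperlike_devtime_params <- function(seed = 1L, vials_per_cell = 8) {
  survival_sim_params(
    beta = c(Intercept = 235.12, SelU = -2.43, SelC = -0.80, StarvS = 4.86,
             `SelU:StarvS` = 1.35, `SelC:StarvS` = 3.83),
    terms = c("Sel", "Starv", "Sel:Starv"),
    sigma_resid = 12, sigma_line = 2, sigma_vial = 3,
    vials_per_cell = vials_per_cell,
    flies_per_vial = c(5, 10),
    schedule = list(pooled = schedule_spec(6, 12, 288)),
    age_range = c(0, 0), age_slope = 0,
    seed = seed
  )
}

#' Treatment-cell design for a survival experiment
#'
#' @param sexes sex labels used (or `"not_applicable"` for pooled designs).
#' @param cues cue labels.
#' @param starvs starvation labels.
#' @return data.frame of treatment cells crossed with regimes.
#' @export
survival_design <- function(sexes = c("F", "M"),
                            cues = c("none", "cold_shock"),
                            starvs = not_applicable()) {
  expand.grid(regime = c("R", "U", "C"), sex = sexes, cue = cues,
              starv = starvs, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

line_ids <- function(n_per_regime) {
  data.frame(
    line_id = sprintf("L%02d", seq_len(3L * n_per_regime)),
    regime = rep(c("R", "U", "C"), each = n_per_regime),
    stringsAsFactors = FALSE
  )
}

#' Simulate an interval-censored survival experiment
#'
#' Draws latent normal event times under the generating model of
#' [survival_sim_params()], bins them into each vial's inspection schedule,
#' and returns the long-format [vial_table()] together with the generating
#' truth (all coefficients including implicit zeros, variance components and
#' the drawn line and vial effects).
#'
#' @param params a [survival_sim_params()].
#' @param design treatment cells, as from [survival_design()]; defaults to the
#'   design implied by `params$terms`.
#' @return list with elements `records` (a `vial_table`) and `truth`.
#' @export
simulate_survival_experiment <- function(params, design = NULL) {
  stopifnot(inherits(params, "survival_sim_params"))
  if (is.null(design)) {
    mains <- unique(unlist(strsplit(params$terms, ":", fixed = TRUE)))
    design <- survival_design(
      sexes  = if ("Sex" %in% mains) c("F", "M") else not_applicable(),
      cues   = if ("Cue" %in% mains) c("none", "cold_shock") else not_applicable(),
      starvs = if ("Starv" %in% mains) c("none", "starved") else not_applicable()
    )
  }
  set.seed(params$seed)
  lines <- line_ids(params$n_lines_per_regime)

  vials <- merge(lines, design, by = "regime", sort = FALSE)
  vials <- vials[rep(seq_len(nrow(vials)), each = params$vials_per_cell), ]
  rownames(vials) <- NULL
  vials$vial_id <- sprintf("V%04d", seq_len(nrow(vials)))
  vials$start_age_h <- stats::runif(nrow(vials), params$age_range[1],
                                    params$age_range[2])
  vials$n_start <- sample.int(
    params$flies_per_vial[2] - params$flies_per_vial[1] + 1L,
    nrow(vials), replace = TRUE
  ) + params$flies_per_vial[1] - 1L

  spec <- model_spec("latent", fixed = params$terms,
                     reference = list(Sel = "R", Sex = "F", Cue = "none",
                                      Starv = "none"))
  dm <- build_design_matrix(vials, spec)
  beta_full <- resolve_beta(params$beta, dm$term_names)
  age_center <- mean(params$age_range)

  u_line <- stats::setNames(stats::rnorm(nrow(lines), 0, params$sigma_line),
                            lines$line_id)
  u_vial <- stats::setNames(stats::rnorm(nrow(vials), 0, params$sigma_vial),
                            vials$vial_id)
  mu_vial <- drop(dm$X %*% beta_full) +
    params$age_slope * (vials$start_age_h - age_center) +
    u_line[vials$line_id] + u_vial[vials$vial_id]

  sched_for <- function(sex) {
    s <- params$schedule[[sex]]
    if (is.null(s)) s <- params$schedule[["pooled"]]
    if (is.null(s)) stop("no schedule defined for sex '", sex, "'")
    make_schedule(s)
  }
  boundaries_by_sex <- lapply(
    stats::setNames(nm = unique(vials$sex)),
    function(sx) sched_for(if (sx == not_applicable()) "pooled" else sx)
  )

  rows <- vector("list", nrow(vials))
  for (i in seq_len(nrow(vials))) {
    b <- boundaries_by_sex[[vials$sex[i]]]
    k <- length(b)
    t_lat <- mu_vial[i] + stats::rnorm(vials$n_start[i], 0, params$sigma_resid)
    # event discovered at the first inspection at or after the latent time;
    # times <= first boundary (incl. negative) fall in the first interval
    bin <- findInterval(t_lat, b, left.open = TRUE) + 1L
    deaths <- tabulate(bin[bin <= k], nbins = k)
    rows[[i]] <- data.frame(
      vial_id = vials$vial_id[i], line_id = vials$line_id[i],
      regime = vials$regime[i], sex = vials$sex[i],
      cue = vials$cue[i], starv = vials$starv[i],
      start_age_h = vials$start_age_h[i], n_start = vials$n_start[i],
      interval_lo_h = c(0, b[-k]), interval_hi_h = b,
      deaths = deaths,
      n_censored = c(rep(NA_integer_, k - 1L), sum(bin > k)),
      stringsAsFactors = FALSE
    )
  }
  records <- vial_table(do.call(rbind, rows))

  truth <- list(beta = beta_full, age_slope = params$age_slope,
                age_center = age_center,
                sigma_resid = params$sigma_resid,
                sigma_line = params$sigma_line, sigma_vial = params$sigma_vial,
                u_line = u_line, u_vial = u_vial, params = params)
  list(records = records, truth = truth)
}

#' Parameters for simulated overdispersed egg counts
#'
#' Egg counts are negative binomial on a log link:
#' `eggs ~ NB(mean = exp(X beta + u_line), shape = dispersion)` with
#' `u_line ~ N(0, sigma_line)` per replicate line (variance =
#' `mu + mu^2 / dispersion`).
#'
#' @param beta named coefficients on the log scale; Table-2-style names with
#'   regime C as reference (`Intercept`, `SelU`, `SelR`, `CueCs`, `StarvS`).
#' @param dispersion negative-binomial shape (> 0); larger is closer to
#'   Poisson.
#' @param sigma_line log-scale SD of the line random intercept.
#' @param females_per_cell females per replicate line within each cue x starv
#'   cell (spread round-robin over the age classes of the model block).
#' @param seed integer seed.
#' @return object of class `count_sim_params`.
#' @export
count_sim_params <- function(beta, dispersion = 5, sigma_line = 0.1,
                             females_per_cell = 5, seed = 1L) {
  stopifnot(dispersion > 0, sigma_line >= 0, females_per_cell >= 1)
  structure(list(beta = beta, dispersion = dispersion, sigma_line = sigma_line,
                 females_per_cell = females_per_cell, seed = as.integer(seed)),
            class = "count_sim_params")
}

#' Default fecundity generating configurations
#'
#' Log-scale coefficients equal the published estimates (regime C reference):
#' early fecundity (4- or 7-day-old females) intercept 2.97 with SelU 0.12,
#' SelR -0.01, CueCs -0.26, StarvS -0.04; mid-life (14 days) intercept 2.56
#' with SelU 0.36, SelR 0.30, CueCs -0.17, StarvS 0.01. Default cell counts
#' give ~340 early and ~290 mid-life females, matching the assay's 339 and
#' 312. Dispersion (5) and line SD (0.1) are generator settings.
#'
#' @param which `"early"` or `"midlife"`.
#' @param seed integer seed.
#' @return a [count_sim_params()] with an `age_classes` attribute.
#' @export
paperlike_fecundity_params <- function(which = c("early", "midlife"), seed = 1L) {
  which <- match.arg(which)
  if (which == "early") {
    p <- count_sim_params(
      beta = c(Intercept = 2.97, SelU = 0.12, SelR = -0.01,
               CueCs = -0.26, StarvS = -0.04),
      dispersion = 5, sigma_line = 0.1, females_per_cell = 5, seed = seed
    )
    attr(p, "age_classes") <- c("early_4d", "early_7d")
  } else {
    p <- count_sim_params(
      beta = c(Intercept = 2.56, SelU = 0.36, SelR = 0.30,
               CueCs = -0.17, StarvS = 0.01),
      dispersion = 5, sigma_line = 0.1, females_per_cell = 4, seed = seed
    )
    attr(p, "age_classes") <- "midlife_14d"
  }
  p
}

#' Simulate per-female egg counts
#'
#' @param params a [count_sim_params()].
#' @param age_classes age classes to cross with the treatment design
#'   (age class labels records only; it is not a generating term).
#' @return list with `records` (a [fecundity_table()]) and `truth`.
#' @export
simulate_fecundity <- function(params,
                               age_classes = attr(params, "age_classes") %||%
                                 "early_4d") {
  stopifnot(inherits(params, "count_sim_params"))
  set.seed(params$seed)
  lines <- line_ids(6L)
  cells <- merge(lines,
                 expand.grid(cue = c("none", "cold_shock"),
                             starv = c("none", "starved"),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
                 by = NULL)
  females <- cells[rep(seq_len(nrow(cells)), each = params$females_per_cell), ]
  rownames(females) <- NULL
  # age classes are recorded labels, spread evenly over each cell's females
  females$age_class <- rep_len(rep(age_classes,
                                   length.out = params$females_per_cell),
                               nrow(females))
  females$female_id <- sprintf("F%04d", seq_len(nrow(females)))
  females$sex <- "F"

  spec <- model_spec("eggs", fixed = c("Sel", "Cue", "Starv"),
                     reference = list(Sel = "C", Cue = "none", Starv = "none"))
  dm <- build_design_matrix(females, spec)
  beta_full <- resolve_beta(params$beta, dm$term_names)
  u_line <- stats::setNames(stats::rnorm(nrow(lines), 0, params$sigma_line),
                            lines$line_id)
  log_mu <- drop(dm$X %*% beta_full) + u_line[females$line_id]
  females$eggs <- stats::rnbinom(nrow(females), mu = exp(log_mu),
                                 size = params$dispersion)

  records <- fecundity_table(
    females[, c("female_id", "line_id", "regime", "cue", "starv",
                "age_class", "eggs")]
  )
  truth <- list(beta = beta_full, dispersion = params$dispersion,
                sigma_line = params$sigma_line, u_line = u_line,
                params = params)
  list(records = records, truth = truth)
}

#' Simulate per-vial egg-to-adult survival outcomes
#'
#' Vial-level binomial outcomes on a logit link:
#' `eclosed ~ Binomial(n_eggs, plogis(X beta + u_line))`.
#'
#' @param beta named logit-scale coefficients (regime C reference by default
#'   via `reference`).
#' @param sigma_line logit-scale line SD.
#' @param vials_per_cell vials per line within each cue x starv cell.
#' @param eggs_per_vial mean eggs per vial; each vial's count is
#'   `1 + Poisson(eggs_per_vial - 1)`.
#' @param reference reference levels (Sel default "C").
#' @param seed integer seed.
#' @return list with `records` (data.frame: vial_id, line_id, regime, cue,
#'   starv, n_eggs, n_eclosed) and `truth`.
#' @export
simulate_eclosion <- function(beta, sigma_line = 0.2, vials_per_cell = 4,
                              eggs_per_vial = 7.6,
                              reference = list(Sel = "C", Cue = "none",
                                               Starv = "none"),
                              seed = 1L) {
  set.seed(as.integer(seed))
  lines <- line_ids(6L)
  vials <- merge(lines,
                 expand.grid(cue = c("none", "cold_shock"),
                             starv = c("none", "starved"),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
                 by = NULL)
  vials <- vials[rep(seq_len(nrow(vials)), each = vials_per_cell), ]
  rownames(vials) <- NULL
  vials$vial_id <- sprintf("E%04d", seq_len(nrow(vials)))
  vials$sex <- not_applicable()

  spec <- model_spec("eclosion", fixed = c("Sel", "Cue", "Starv"),
                     reference = reference)
  dm <- build_design_matrix(vials, spec)
  beta_full <- resolve_beta(beta, dm$term_names)
  u_line <- stats::setNames(stats::rnorm(nrow(lines), 0, sigma_line),
                            lines$line_id)
  p <- stats::plogis(drop(dm$X %*% beta_full) + u_line[vials$line_id])
  vials$n_eggs <- 1L + stats::rpois(nrow(vials), max(eggs_per_vial - 1, 0))
  vials$n_eclosed <- stats::rbinom(nrow(vials), vials$n_eggs, p)

  records <- vials[, c("vial_id", "line_id", "regime", "cue", "starv",
                       "n_eggs", "n_eclosed")]
  truth <- list(beta = beta_full, sigma_line = sigma_line, u_line = u_line,
                p = p)
  list(records = records, truth = truth)
}

#' Simulate one-measurement-per-line physiology traits
#'
#' One record per replicate line x sex x trait. Each value is the cell mean
#' plus a per-line deviation shared by the line's two sex measurements (SD
#' `sigma_between_line`) plus, optionally, an independent within-line residual
#' (SD `sigma_within`).
#'
#' @param cell_means data.frame with columns `trait`, `regime`, `sex`, `mean`.
#' @param sigma_between_line between-line SD (>= 0).
#' @param sigma_within residual SD (default 0: values equal cell mean + line
#'   deviation exactly).
#' @param n_lines_per_regime replicate lines per regime.
#' @param seed integer seed.
#' @return list with `records` (a [line_trait_table()]) and `truth`.
#' @export
simulate_line_traits <- function(cell_means, sigma_between_line,
                                 sigma_within = 0,
                                 n_lines_per_regime = 6, seed = 1L) {
  stopifnot(sigma_between_line >= 0, sigma_within >= 0)
  set.seed(as.integer(seed))
  lines <- line_ids(n_lines_per_regime)
  out <- list()
  truth_u <- list()
  for (tr in unique(cell_means$trait)) {
    cm <- cell_means[cell_means$trait == tr, , drop = FALSE]
    u_line <- stats::setNames(stats::rnorm(nrow(lines), 0, sigma_between_line),
                              lines$line_id)
    grid <- merge(lines, unique(cm[, c("regime", "sex")]), by = "regime",
                  sort = FALSE)
    grid <- merge(grid, cm, by = c("regime", "sex"), sort = FALSE)
    grid$value <- grid$mean + u_line[grid$line_id] +
      stats::rnorm(nrow(grid), 0, sigma_within)
    grid$trait <- tr
    out[[tr]] <- grid[, c("line_id", "regime", "sex", "trait", "value")]
    truth_u[[tr]] <- u_line
  }
  records <- line_trait_table(do.call(rbind, out))
  list(records = records,
       truth = list(u_line = truth_u, sigma_between_line = sigma_between_line,
                    sigma_within = sigma_within))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
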