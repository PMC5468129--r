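# Interval-censored normal likelihood. These are the reference (pure-R)
# implementations; the sampler uses a compiled log-posterior/gradient that is
# tested against them.

# log(exp(la) - exp(lb)) for la > lb, stable for la - lb small or large
log_diff_exp <- function(la, lb) {
  la + log1p(-exp(lb - la))
}

#' Log probability of a normal variate falling in an interval
#'
#' `log[ Phi((hi - mu)/sigma) - Phi((lo - mu)/sigma) ]`, evaluated in the
#' appropriate tail so that it stays accurate far from the mean. `hi = Inf`
#' gives the right-censoring term `log[1 - Phi((lo - mu)/sigma)]`; `lo = -Inf`
#' the left tail. All arguments recycle.
#'
#' @param mu,sigma mean and SD of the latent event time (hours); `sigma > 0`.
#' @param lo,hi interval bounds (hours), `lo < hi`; infinite bounds allowed.
#' @return log probability (vectorized).
#' @export
interval_log_prob <- function(mu, sigma, lo, hi) {
  if (min(length(mu), length(sigma), length(lo), length(hi)) == 0L) {
    return(numeric(0))
  }
  n <- max(length(mu), length(sigma), length(lo), length(hi))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(lo >= hi)) stop("interval bounds must satisfy lo < hi")

  z_lo <- (lo - mu) / sigma
  z_hi <- (hi - mu) / sigma
  out <- numeric(n)

  both_inf <- is.infinite(z_lo) & is.infinite(z_hi)
  right <- !both_inf & is.infinite(z_hi)           # right censoring
  left <- !both_inf & is.infinite(z_lo)            # left tail
  upper <- !both_inf & !right & !left & z_lo >= 0  # both bounds in upper tail
  lower <- !both_inf & !right & !left & z_hi <= 0  # both in lower tail
  mid <- !(both_inf | right | left | upper | lower)

  out[both_inf] <- 0
  out[right] <- stats::pnorm(z_lo[right], lower.tail = FALSE, log.p = TRUE)
  out[left] <- stats::pnorm(z_hi[left], log.p = TRUE)
  if (any(upper)) {
    out[upper] <- log_diff_exp(
      stats::pnorm(z_lo[upper], lower.tail = FALSE, log.p = TRUE),
      stats::pnorm(z_hi[upper], lower.tail = FALSE, log.p = TRUE)
    )
  }
  if (any(lower)) {
    out[lower] <- log_diff_exp(
      stats::pnorm(z_hi[lower], log.p = TRUE),
      stats::pnorm(z_lo[lower], log.p = TRUE)
    )
  }
  if (any(mid)) {
    out[mid] <- log(stats::pnorm(z_hi[mid]) - stats::pnorm(z_lo[mid]))
  }
  out
}

# flatten a vial table into likelihood rows: one row per vial x interval with
# positive weight, plus one right-censoring row per vial with censored > 0.
# Returns vial-level design info shared by the R and compiled paths.
prepare_likelihood_data <- function(records, spec, age_center = NULL) {
  df <- as.data.frame(records)
  vs <- vial_starts(df)
  dm <- build_design_matrix(vs, spec, age_center = age_center)

  lo <- df$interval_lo_h
  # an event discovered at the first inspection is only known to precede it:
  # the first interval is open on the left (negative latent times included)
  lo[lo == 0] <- -Inf
  hi <- df$interval_hi_h
  w <- as.numeric(df$deaths)
  vial_of_row <- match(df$vial_id, vs$vial_id)

  last <- !duplicated(df$vial_id, fromLast = TRUE)
  cens_w <- as.numeric(df$n_censored[last])
  cens_lo <- df$interval_hi_h[last]
  cens_vial <- match(df$vial_id[last], vs$vial_id)

  lo <- c(lo, cens_lo)
  hi <- c(hi, rep(Inf, length(cens_lo)))
  w <- c(w, cens_w)
  vial_of_row <- c(vial_of_row, cens_vial)

  keep <- w > 0
  if (spec$family == "lognormal") {
    if (any(lo[keep] < 0)) stop("lognormal family requires non-negative boundaries")
    lo <- ifelse(lo <= 0, -Inf, log(lo))
    hi <- ifelse(is.infinite(hi), Inf, log(hi))
  }

  line_levels <- sort(unique(vs$line_id))
  list(
    X = dm$X, term_names = dm$term_names, age_center = dm$age_center,
    lo = lo[keep], hi = hi[keep], w = w[keep],
    vial_of_row = vial_of_row[keep],
    vial_ids = vs$vial_id, line_ids = vs$line_id,
    line_levels = line_levels,
    line_of_vial = match(vs$line_id, line_levels),
    n_vial = nrow(vs), n_line = length(line_levels)
  )
}

#' Interval-censored log-likelihood of a vial dataset
#'
#' Sums, over vials and inspection intervals, `deaths * interval_log_prob` at
#' the vial's mean `mu = X beta + u_line + u_vial`, plus each vial's
#' right-censoring term `n_censored * log[1 - Phi((last boundary - mu)/sigma)]`.
#'
#' @param beta coefficient vector (named, resolved against the spec's design;
#'   or unnamed of full design length).
#' @param sigmas list with `resid` (> 0); line and vial SDs do not enter the
#'   likelihood (they are priors on the group effects).
#' @param group_effects list with numeric vectors `line` and/or `vial`, named
#'   by line and vial ids; must cover every group present in `records`.
#'   Missing components are treated as structurally absent (all zero).
#' @param records a [vial_table()].
#' @param spec a [model_spec()].
#' @return the log-likelihood (scalar).
#' @export
dataset_log_likelihood <- function(beta, sigmas, group_effects, records, spec) {
  ld <- prepare_likelihood_data(records, spec)
  p <- length(ld$term_names)
  if (!is.null(names(beta))) {
    beta <- resolve_beta(beta, ld$term_names)
  } else if (length(beta) != p) {
    stop("beta must be named or have length ", p)
  }
  u_line <- rep(0, ld$n_vial)
  if ("line" %in% spec$random) {
    ul <- group_effects$line
    if (is.null(ul) || !all(ld$line_levels %in% names(ul))) {
      stop("group_effects$line must provide one value per line: ",
           paste(setdiff(ld$line_levels, names(ul)), collapse = ", "))
    }
    u_line <- unname(ul[ld$line_ids])
  }
  u_vial <- rep(0, ld$n_vial)
  if ("vial" %in% spec$random) {
    uv <- group_effects$vial
    if (is.null(uv) || !all(ld$vial_ids %in% names(uv))) {
      stop("group_effects$vial must provide one value per vial")
    }
    u_vial <- unname(uv[ld$vial_ids])
  }
  mu <- drop(ld$X %*% beta) + u_line + u_vial
  sum(ld$w * interval_log_prob(mu[ld$vial_of_row], sigmas$resid, ld$lo, ld$hi))
}

#' Log posterior density of the interval-censored mixed model
#'
#' `dataset_log_likelihood` plus the normal log densities of the group
#' effects (`u_line ~ N(0, sigma_line)`, `u_vial ~ N(0, sigma_vial)`) and the
#' priors: independent `N(0, beta_scale)` on each coefficient and half-normal
#' `(0, sigma_scale)` on each SD. Densities are evaluated on the natural
#' (sigma) scale.
#'
#' @param params list with `beta` (named or full-length), `sigma_resid`,
#'   and per random group `sigma_line`/`u_line`, `sigma_vial`/`u_vial`.
#' @param records a [vial_table()].
#' @param spec a [model_spec()]; `spec$priors` must hold resolved numeric
#'   `beta_scale` and `sigma_scale` (see [default_prior_scales()]).
#' @return log posterior density (unnormalized), scalar.
#' @export
log_posterior <- function(params, records, spec) {
  pr <- resolved_prior_scales(spec, records)
  ld <- prepare_likelihood_data(records, spec)
  lp <- log_posterior_core(params, ld, spec, pr)
  if (!is.finite(lp)) {
    stop("non-finite log posterior (check sigmas > 0 and group effects)")
  }
  lp
}

# shared core working from prepared likelihood data; returns -Inf rather than
# erroring so quadrature can sweep degenerate corners of a grid
log_posterior_core <- function(params, ld, spec, pr) {
  beta <- if (!is.null(names(params$beta))) {
    resolve_beta(params$beta, ld$term_names)
  } else params$beta
  if (is.null(params$sigma_resid) || params$sigma_resid <= 0) return(-Inf)

  u_line_v <- rep(0, ld$n_vial)
  if ("line" %in% spec$random) {
    ul <- params$u_line
    if (is.null(ul) || !all(ld$line_levels %in% names(ul))) {
      stop("params$u_line must provide one value per line")
    }
    u_line_v <- unname(ul[ld$line_ids])
  }
  u_vial_v <- rep(0, ld$n_vial)
  if ("vial" %in% spec$random) {
    uv <- params$u_vial
    if (is.null(uv) || !all(ld$vial_ids %in% names(uv))) {
      stop("params$u_vial must provide one value per vial")
    }
    u_vial_v <- unname(uv[ld$vial_ids])
  }
  mu <- drop(ld$X %*% beta) + u_line_v + u_vial_v
  lp <- sum(ld$w * interval_log_prob(mu[ld$vial_of_row], params$sigma_resid,
                                     ld$lo, ld$hi))
  beta_scale <- rep_len(pr$beta_scale, length(beta))
  lp <- lp + sum(stats::dnorm(beta, 0, beta_scale, log = TRUE))
  lp <- lp + half_normal_log(params$sigma_resid, pr$sigma_scale[1])
  if ("line" %in% spec$random) {
    lp <- lp + half_normal_log(params$sigma_line, pr$sigma_scale[2]) +
      sum(stats::dnorm(params$u_line, 0, params$sigma_line, log = TRUE))
  }
  if ("vial" %in% spec$random) {
    lp <- lp + half_normal_log(params$sigma_vial, pr$sigma_scale[3]) +
      sum(stats::dnorm(params$u_vial, 0, params$sigma_vial, log = TRUE))
  }
  lp
}

half_normal_log <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

#' Default prior scales from the data
#'
#' A crude response SD is taken from event-interval midpoints (censored
#' individuals contribute their last boundary, a lower bound): coefficients
#' get `N(0, 10 * SD)` priors and each SD a half-normal with scale `SD`.
#' Weakly informative on the hours scale, dominated by datasets of assay size.
#'
#' @param records a [vial_table()].
#' @param spec a [model_spec()] (for the response family).
#' @return list with `beta_scale` and `sigma_scale` (length 3:
#'   residual, line, vial).
#' @export
default_prior_scales <- function(records, spec = NULL) {
  df <- as.data.frame(records)
  mid <- (df$interval_lo_h + df$interval_hi_h) / 2
  if (!is.null(spec) && spec$family == "lognormal") mid <- log(pmax(mid, 1e-6))
  last <- !duplicated(df$vial_id, fromLast = TRUE)
  vals <- c(rep(mid, pmax(df$deaths, 0)),
            rep(if (!is.null(spec) && spec$family == "lognormal")
                  log(pmax(df$interval_hi_h[last], 1e-6))
                else df$interval_hi_h[last],
                pmax(df$n_censored[last], 0)))
  s <- stats::sd(vals)
  if (!is.finite(s) || s <= 0) s <- 1
  list(beta_scale = 10 * s, sigma_scale = rep(s, 3))
}

resolved_prior_scales <- function(spec, records) {
  pr <- spec$priors
  if (is.null(pr$beta_scale) || is.null(pr$sigma_scale)) {
    def <- default_prior_scales(records, spec)
    if (is.null(pr$beta_scale)) pr$beta_scale <- def$beta_scale
    if (is.null(pr$sigma_scale)) pr$sigma_scale <- def$sigma_scale
  }
  if (length(pr$sigma_scale) == 1L) pr$sigma_scale <- rep(pr$sigma_scale, 3)
  pr
}
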