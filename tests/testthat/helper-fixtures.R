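# Shared fixtures: small hand-built vial tables and an independent normal-CDF
# oracle built on the error function (pracma), kept separate from the
# package's pnorm-based code path.

phi_oracle <- function(z) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    0.5 * (1 + pracma::erf(z / sqrt(2)))
  } else {
    stats::pnorm(z)  # fallback; the erf route is preferred when available
  }
}

# upper-tail complement, kept well-conditioned deep in the tail
phi_upper_oracle <- function(z) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    0.5 * pracma::erfc(z / sqrt(2))
  } else {
    stats::pnorm(z, lower.tail = FALSE)
  }
}

# interval mass evaluated in whichever tail avoids cancellation, so the
# oracle itself is accurate enough for 1e-10 comparisons
interval_prob_oracle <- function(mu, sigma, lo, hi) {
  z_lo <- if (is.infinite(lo)) -Inf else (lo - mu) / sigma
  z_hi <- if (is.infinite(hi)) Inf else (hi - mu) / sigma
  if (is.infinite(z_lo) && is.infinite(z_hi)) return(1)
  if (is.infinite(z_hi)) return(phi_upper_oracle(z_lo))
  if (is.infinite(z_lo)) return(phi_oracle(z_hi))
  if (z_lo >= 0) return(phi_upper_oracle(z_lo) - phi_upper_oracle(z_hi))
  if (z_hi <= 0) return(phi_upper_oracle(-z_hi) - phi_upper_oracle(-z_lo))
  phi_oracle(z_hi) - phi_oracle(z_lo)
}

# one vial in the long layout; boundaries are the inspection times
make_vial_rows <- function(vial_id, boundaries, deaths, n_censored,
                           line_id = "L01", regime = "R", sex = "F",
                           cue = "none", starv = not_applicable(),
                           start_age_h = 0) {
  k <- length(boundaries)
  data.frame(
    vial_id = vial_id, line_id = line_id, regime = regime, sex = sex,
    cue = cue, starv = starv, start_age_h = start_age_h,
    n_start = sum(deaths) + n_censored,
    interval_lo_h = c(0, boundaries[-k]), interval_hi_h = boundaries,
    deaths = deaths,
    n_censored = c(rep(NA_integer_, k - 1L), n_censored),
    stringsAsFactors = FALSE
  )
}

toy_vial_table <- function() {
  vial_table(rbind(
    make_vial_rows("V1", c(24, 48, 72, 96), c(1, 3, 4, 1), 1),
    make_vial_rows("V2", c(24, 48, 72, 96), c(0, 4, 3, 2), 1)
  ))
}

toy_spec <- function(...) {
  model_spec("toy", fixed = character(0), random = character(0),
             priors = list(beta_scale = 100, sigma_scale = 50), ...)
}

# small simulated survival experiment (72 vials) for fast end-to-end tests
small_sim_params <- function(seed = 1L) {
  survival_sim_params(
    beta = c(Intercept = 60, SexM = -10, CueCs = -5),
    terms = c("Sex", "Cue"),
    sigma_resid = 10, sigma_line = 2, sigma_vial = 3,
    vials_per_cell = 1, flies_per_vial = c(10, 14),
    schedule = list(F = schedule_spec(6, 12, 96), M = schedule_spec(6, 12, 96)),
    age_range = c(90, 100), seed = seed
  )
}
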