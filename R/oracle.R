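# Deterministic quadrature oracle for sampler validation: posterior moments
# of at most two free parameters by brute-force integration on a bounded
# grid, all other parameters held fixed. Shares log_posterior() with nothing
# in the sampler path, so agreement between the two is an end-to-end check.

#' Posterior moments by deterministic grid quadrature
#'
#' Restricts the model to at most two free parameters (any coefficient by
#' name, or `sigma_resid`) with every other parameter fixed, evaluates the
#' exact unnormalized posterior on a uniform grid, and returns normalized
#' means and SDs. Intended as an independent oracle for [fit_mcmc()] on toy
#' problems, not as an estimation routine.
#'
#' @param records a [vial_table()].
#' @param spec a [model_spec()].
#' @param free named list of grid ranges, e.g.
#'   `list(Intercept = c(60, 140), sigma_resid = c(1, 60))`; at most 2 entries.
#' @param fixed list of fixed values: `beta` (named vector for coefficients
#'   not in `free`; omitted coefficients are 0), `sigma_resid`, `sigma_line`,
#'   `sigma_vial`, `u_line`, `u_vial` as the spec requires.
#' @param grid_points grid points per dimension.
#' @return list with per-parameter `mean` and `sd` (named vectors), the grid
#'   and the normalized marginals.
#' @export
grid_posterior_oracle <- function(records, spec, free, fixed = list(),
                                  grid_points = 201L) {
  if (length(free) > 2L) {
    stop("unsupported: the grid oracle handles at most 2 free parameters")
  }
  if (length(free) == 0L) stop("no free parameters given")
  ld <- prepare_likelihood_data(records, spec)
  pr <- resolved_prior_scales(spec, records)
  term_names <- ld$term_names

  base_beta <- if (is.null(fixed$beta)) {
    stats::setNames(numeric(length(term_names)), term_names)
  } else {
    resolve_beta(fixed$beta, term_names)
  }

  make_params <- function(vals) {
    beta <- base_beta
    sigma_resid <- fixed$sigma_resid
    for (nm in names(vals)) {
      if (nm %in% term_names) beta[nm] <- vals[[nm]]
      else if (nm == "sigma_resid") sigma_resid <- vals[[nm]]
      else stop("free parameter '", nm, "' is neither a design term nor sigma_resid")
    }
    list(beta = beta, sigma_resid = sigma_resid,
         sigma_line = fixed$sigma_line, u_line = fixed$u_line,
         sigma_vial = fixed$sigma_vial, u_vial = fixed$u_vial)
  }

  grids <- lapply(free, function(r) seq(r[1], r[2], length.out = grid_points))
  eval_lp <- function(vals) {
    lp <- log_posterior_core(make_params(vals), ld, spec, pr)
    if (!is.finite(lp)) -Inf else lp
  }

  if (length(free) == 1L) {
    nm <- names(free)[1]
    lp <- vapply(grids[[1]], function(v) eval_lp(stats::setNames(list(v), nm)),
                 numeric(1))
    post <- exp(lp - max(lp))
    post <- post / sum(post)
    mean1 <- sum(post * grids[[1]])
    sd1 <- sqrt(sum(post * (grids[[1]] - mean1)^2))
    return(list(mean = stats::setNames(mean1, nm),
                sd = stats::setNames(sd1, nm),
                grid = grids, marginals = stats::setNames(list(post), nm)))
  }

  nm1 <- names(free)[1]; nm2 <- names(free)[2]
  lp <- matrix(NA_real_, grid_points, grid_points)
  for (i in seq_len(grid_points)) {
    for (j in seq_len(grid_points)) {
      lp[i, j] <- eval_lp(stats::setNames(list(grids[[1]][i], grids[[2]][j]),
                                          c(nm1, nm2)))
    }
  }
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  m1 <- rowSums(post); m2 <- colSums(post)
  mean1 <- sum(m1 * grids[[1]]); mean2 <- sum(m2 * grids[[2]])
  list(
    mean = stats::setNames(c(mean1, mean2), c(nm1, nm2)),
    sd = stats::setNames(
      c(sqrt(sum(m1 * (grids[[1]] - mean1)^2)),
        sqrt(sum(m2 * (grids[[2]] - mean2)^2))),
      c(nm1, nm2)
    ),
    grid = grids,
    marginals = stats::setNames(list(m1, m2), c(nm1, nm2))
  )
}
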