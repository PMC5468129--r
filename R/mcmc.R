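# Hamiltonian Monte Carlo for the interval-censored mixed model. Static HMC
# with jittered path length, dual-averaging step-size adaptation and a
# diagonal mass matrix estimated during warmup; group effects are sampled
# non-centered (u = sigma * z) and SDs on the log scale, with the compiled
# log posterior/gradient of src/ic_posterior.cpp.

#' Fit the interval-censored mixed survival model by MCMC
#'
#' Samples the joint posterior of the fixed effects, the residual SD, the
#' line and vial SDs and all group effects. Convergence is checked with
#' split-chain R-hat and effective sample size on the fixed effects and SDs;
#' problems are attached as warnings on the result, never silently dropped.
#'
#' @param records a [vial_table()].
#' @param spec a [model_spec()].
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup,iter warmup and retained iterations per chain.
#' @param seed integer seed; runs are reproducible given `seed`.
#' @param control list: `max_leapfrog` (default 96), `target_accept` (0.9),
#'   `rhat_limit` (1.05), `ess_limit` (100).
#' @return object of class `posterior_draws`: `draws` (iterations x chains x
#'   parameters array on the natural scale), `param_names`, `term_names`,
#'   `spec`, `age_center`, `seed`, sampler settings and `warnings`.
#' @export
fit_mcmc <- function(records, spec, chains = 4L, warmup = 1000L, iter = 1000L,
                     seed = 1L, control = list()) {
  if (chains < 2L) stop("chains must be >= 2 (required for diagnostics)")
  ctl <- utils::modifyList(
    list(max_leapfrog = 96L, target_accept = 0.9,
         rhat_limit = 1.05, ess_limit = 100),
    control
  )
  report <- validate_vial_table(records)
  if (nrow(report) > 0L) {
    stop("invalid dataset:\n", format_validation_report(report))
  }

  ld <- prepare_likelihood_data(records, spec)
  pr <- resolved_prior_scales(spec, records)
  p <- length(ld$term_names)
  beta_scale <- rep_len(pr$beta_scale, p)
  has_line <- "line" %in% spec$random
  has_vial <- "vial" %in% spec$random
  L <- if (has_line) ld$n_line else 0L
  V <- if (has_vial) ld$n_vial else 0L
  d <- p + 1L + has_line + has_vial + L + V

  param_names <- c(
    ld$term_names, "sigma_resid",
    if (has_line) "sigma_line", if (has_vial) "sigma_vial",
    if (has_line) paste0("u_line:", ld$line_levels),
    if (has_vial) paste0("u_vial:", ld$vial_ids)
  )

  logpost <- function(theta) {
    .icmix_logpost_grad(theta, ld$X, ld$vial_of_row - 1L, ld$lo, ld$hi, ld$w,
                        ld$line_of_vial - 1L, ld$n_line, has_line, has_vial,
                        beta_scale, pr$sigma_scale)
  }

  # crude center/scale of observed event times for initialization
  # (first intervals are left-open: use their upper bound)
  mid <- ifelse(is.finite(ld$hi),
                ifelse(is.finite(ld$lo), (ld$lo + ld$hi) / 2, ld$hi),
                ld$lo)
  m0 <- stats::weighted.mean(mid, ld$w)
  s0 <- max(sqrt(stats::weighted.mean((mid - m0)^2, ld$w)), 1e-3)

  sim <- array(NA_real_, dim = c(iter, chains, d),
               dimnames = list(NULL, NULL, param_names))
  accept <- numeric(chains)
  divergences <- integer(chains)
  stepsizes <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed((as.integer(seed) + ch * 7919L) %% 2147483647L)
    theta <- numeric(d)
    theta[1:p] <- c(m0, rep(0, p - 1L)) + stats::rnorm(p, 0, 0.02 * s0)
    idx <- p + 1L
    theta[idx] <- log(s0 * 0.8) + stats::rnorm(1, 0, 0.05)
    if (has_line) { idx <- idx + 1L; theta[idx] <- log(s0 / 10) + stats::rnorm(1, 0, 0.05) }
    if (has_vial) { idx <- idx + 1L; theta[idx] <- log(s0 / 10) + stats::rnorm(1, 0, 0.05) }
    if (L + V > 0L) theta[(idx + 1L):d] <- stats::rnorm(L + V, 0, 0.1)

    out <- hmc_chain(theta, logpost, warmup = warmup, iter = iter, ctl = ctl)
    accept[ch] <- out$accept_rate
    divergences[ch] <- out$divergences
    stepsizes[ch] <- out$stepsize
    draws <- out$draws  # iter x d, unconstrained

    # transform to the natural scale: sigmas exp'd, u = sigma * z
    draws[, p + 1L] <- exp(draws[, p + 1L])
    col <- p + 1L
    if (has_line) { col <- col + 1L; draws[, col] <- exp(draws[, col]) }
    if (has_vial) { col <- col + 1L; draws[, col] <- exp(draws[, col]) }
    if (has_line) {
      zc <- (col + 1L):(col + L)
      draws[, zc] <- draws[, zc] * draws[, p + 2L]
      col <- col + L
    }
    if (has_vial) {
      zc <- (col + 1L):(col + V)
      draws[, zc] <- draws[, zc] * draws[, p + 1L + has_line + 1L]
      col <- col + V
    }
    sim[, ch, ] <- draws
  }

  res <- structure(
    list(draws = sim, param_names = param_names, term_names = ld$term_names,
         spec = spec, age_center = ld$age_center, seed = as.integer(seed),
         chains = chains, warmup = warmup, iter = iter,
         prior_scales = list(beta_scale = beta_scale,
                             sigma_scale = pr$sigma_scale),
         accept_rate = accept, divergences = divergences,
         stepsize = stepsizes, warnings = character()),
    class = "posterior_draws"
  )

  core <- c(ld$term_names, "sigma_resid",
            if (has_line) "sigma_line", if (has_vial) "sigma_vial")
  diag <- summarize(res)
  diag <- diag[diag$term %in% core, , drop = FALSE]
  msgs <- character()
  if (any(diag$rhat > ctl$rhat_limit, na.rm = TRUE)) {
    bad <- diag$term[which(diag$rhat > ctl$rhat_limit)]
    msgs <- c(msgs, paste0("convergence: rhat > ", ctl$rhat_limit, " for ",
                           paste(bad, collapse = ", ")))
  }
  if (any(diag$ess < ctl$ess_limit, na.rm = TRUE)) {
    bad <- diag$term[which(diag$ess < ctl$ess_limit)]
    msgs <- c(msgs, paste0("low effective sample size (< ", ctl$ess_limit,
                           ") for ", paste(bad, collapse = ", ")))
  }
  if (sum(divergences) > 0L) {
    msgs <- c(msgs, sprintf("%d divergent transitions", sum(divergences)))
  }
  res$warnings <- msgs
  for (m in msgs) warning(m, call. = FALSE)
  res
}

# one HMC chain on the unconstrained scale; returns kept draws and stats
hmc_chain <- function(theta, logpost, warmup, iter, ctl) {
  d <- length(theta)
  inv_mass <- rep(1, d)
  cur <- logpost(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at the initial point")

  # initial step size: one-leapfrog acceptance crossing 0.5, fixed momentum,
  # direction chosen once so the search cannot oscillate
  p0 <- stats::rnorm(d) / sqrt(inv_mass)
  step_dh <- function(e) {
    s <- leapfrog(theta, p0, e, 1L, inv_mass, logpost, cur)
    if (!is.finite(s$h_new)) -Inf else s$h0 - s$h_new
  }
  eps <- 0.1
  dh <- step_dh(eps)
  while (!is.finite(dh) && eps > 1e-10) {
    eps <- eps / 10
    dh <- step_dh(eps)
  }
  dir <- if (dh > log(0.5)) 1 else -1
  repeat {
    eps_next <- eps * 2^dir
    if (eps_next < 1e-10 || eps_next > 1e3) break
    dh <- step_dh(eps_next)
    crossed_up <- dir == 1 && !(is.finite(dh) && dh > log(0.5))
    crossed_down <- dir == -1 && is.finite(dh) && dh > log(0.5)
    if (crossed_up) break
    eps <- eps_next
    if (crossed_down) break
  }

  # dual averaging setup
  da_mu <- log(10 * eps); da_h <- 0; da_logeps_bar <- log(eps); da_count <- 0
  da_reset <- function() {
    da_mu <<- log(10 * eps); da_h <<- 0; da_logeps_bar <<- log(eps); da_count <<- 0
  }
  da_update <- function(alpha) {
    da_count <<- da_count + 1
    frac <- 1 / (da_count + 10)
    da_h <<- (1 - frac) * da_h + frac * (ctl$target_accept - alpha)
    logeps <- da_mu - sqrt(da_count) / 0.05 * da_h
    wt <- da_count^(-0.75)
    da_logeps_bar <<- wt * logeps + (1 - wt) * da_logeps_bar
    eps <<- exp(logeps)
  }

  w1 <- max(20L, floor(0.15 * warmup))
  w2_end <- floor(0.85 * warmup)
  mass_buf <- matrix(NA_real_, nrow = max(w2_end - w1, 1L), ncol = d)
  buf_n <- 0L

  draws <- matrix(NA_real_, nrow = iter, ncol = d)
  n_accept <- 0; n_div <- 0L

  total <- warmup + iter
  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    n_leap <- sample.int(ctl$max_leapfrog, 1L)
    n_leap <- max(n_leap, ceiling(ctl$max_leapfrog / 2))
    step <- leapfrog(theta, p0, eps, n_leap, inv_mass, logpost, cur)
    if (is.finite(step$h_new)) {
      dh <- step$h0 - step$h_new
      if (dh < -1000) { n_div <- n_div + 1L; alpha <- 0 }
      else {
        alpha <- min(1, exp(dh))
        if (stats::runif(1) < alpha) {
          theta <- step$theta; cur <- step$cache
          if (it > warmup) n_accept <- n_accept + 1
        }
      }
    } else {
      n_div <- n_div + 1L
      alpha <- 0
    }

    if (it <= warmup) {
      da_update(alpha)
      if (it > w1 && it <= w2_end) {
        buf_n <- buf_n + 1L
        mass_buf[buf_n, ] <- theta
      }
      if (it == w2_end && buf_n > 10L) {
        v <- apply(mass_buf[seq_len(buf_n), , drop = FALSE], 2, stats::var)
        inv_mass <- (buf_n / (buf_n + 5)) * v + (5 / (buf_n + 5)) * 1e-3
        inv_mass[inv_mass < 1e-8] <- 1e-8
        da_reset()
      }
      if (it == warmup) eps <- exp(da_logeps_bar)
    } else {
      draws[it - warmup, ] <- theta
    }
  }

  list(draws = draws, accept_rate = n_accept / iter, divergences = n_div,
       stepsize = eps)
}

leapfrog <- function(theta, p, eps, n_steps, inv_mass, logpost, cache0) {
  h0 <- -cache0$lp + 0.5 * sum(p^2 * inv_mass)
  g <- cache0$grad
  for (s in seq_len(n_steps)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * inv_mass * p
    cache <- logpost(theta)
    if (!is.finite(cache$lp)) {
      return(list(theta = theta, h0 = h0, h_new = Inf, cache = cache))
    }
    g <- cache$grad
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, h0 = h0, h_new = -cache$lp + 0.5 * sum(p^2 * inv_mass),
       cache = cache)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s: %d chains x %d iterations, %d parameters\n",
              x$spec$response, x$chains, x$iter, length(x$param_names)))
  cat(sprintf("  accept rate %.2f, %d divergences, step sizes %s\n",
              mean(x$accept_rate), sum(x$divergences),
              paste(signif(x$stepsize, 3), collapse = "/")))
  if (length(x$warnings) > 0L) {
    cat("  WARNINGS:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  }
  print(utils::head(summarize(x), length(x$term_names) + 3L))
  invisible(x)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, equal-tailed 95% credible interval, split
#' chain R-hat and effective sample size, and a significance flag (the
#' interval excludes zero) -- the machine-readable twin of an effect table.
#'
#' @param draws a `posterior_draws` object, or an iterations x chains x
#'   parameters array.
#' @param prob credible mass (default 0.95, equal-tailed).
#' @return data.frame with columns `term`, `mean`, `ci_low`, `ci_high`,
#'   `rhat`, `ess`, `significant`. With a single chain, `rhat` and `ess` are
#'   `NA` (unavailable).
#' @export
summarize <- function(draws, prob = 0.95) {
  arr <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(length(dim(arr)) == 3L)
  pn <- dimnames(arr)[[3]]
  if (is.null(pn)) pn <- paste0("param", seq_len(dim(arr)[3]))
  a <- (1 - prob) / 2
  out <- lapply(seq_len(dim(arr)[3]), function(j) {
    x <- arr[, , j, drop = FALSE]
    flat <- as.vector(x)
    ci <- unname(stats::quantile(flat, c(a, 1 - a), names = FALSE))
    data.frame(
      term = pn[j], mean = mean(flat), ci_low = ci[1], ci_high = ci[2],
      rhat = split_rhat(x[, , 1]), ess = ess_bulk(x[, , 1]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out
}

# split-chain R-hat (BDA3); x is an iterations x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L && nrow(x) < 4L) return(NA_real_)
  if (ncol(x) == 1L) return(NA_real_)
  half <- floor(nrow(x) / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1L):nrow(x), , drop = FALSE])
  n <- nrow(xs); m <- ncol(xs)
  means <- colMeans(xs)
  if (stats::var(means) == 0 && all(apply(xs, 2, stats::var) == 0)) return(1)
  b <- n * stats::var(means)
  w <- mean(apply(xs, 2, stats::var))
  if (w == 0) return(Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# bulk effective sample size via Geyer's initial monotone positive sequence
ess_bulk <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2L || n < 8L) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  n <- nrow(xs); m <- ncol(xs)
  chain_var <- apply(xs, 2, stats::var)
  if (all(chain_var == 0)) return(NA_real_)
  b <- n * stats::var(colMeans(xs))
  w <- mean(chain_var)
  var_plus <- (n - 1) / n * w + b / n
  lag_max <- min(n - 2L, 200L)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(xs[, j], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)  # lag 0..lag_max
  rho <- 1 - (w - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive and monotone
  tau <- 1
  k <- 1
  prev_pair <- Inf
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    k <- k + 2
  }
  max(m * n / tau, 1e-3)
}
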