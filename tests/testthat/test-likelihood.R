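# Interval-censored likelihood and log posterior

test_that("interval_log_prob matches its closed forms", {
  expect_equal(interval_log_prob(13, 4, -Inf, Inf), 0)
  expect_equal(interval_log_prob(100, 10, 100, Inf), log(0.5), tolerance = 1e-12)
  expect_equal(interval_log_prob(100, 10, 90, 110),
               log(interval_prob_oracle(100, 10, 90, 110)),
               tolerance = 1e-12)
  expect_equal(interval_log_prob(100, 10, 90, 110), log(0.682689), tolerance = 1e-5)
})

test_that("interval_log_prob survives deep tails where naive CDF differences fail", {
  lp <- interval_log_prob(0, 1, 10, 12)
  expect_true(is.finite(lp))
  expect_equal(lp, stats::pnorm(10, lower.tail = FALSE, log.p = TRUE) +
                 log1p(-exp(stats::pnorm(12, lower.tail = FALSE, log.p = TRUE) -
                              stats::pnorm(10, lower.tail = FALSE, log.p = TRUE))),
               tolerance = 1e-12)
  expect_lt(interval_log_prob(0, 1, 35, 36), -600)
})

test_that("exponentiated interval probabilities over any partition sum to one", {
  set.seed(101)
  for (i in 1:25) {
    mu <- runif(1, -50, 150)
    sigma <- runif(1, 0.5, 40)
    cuts <- sort(runif(sample(2:12, 1), mu - 5 * sigma, mu + 5 * sigma))
    bounds <- c(-Inf, cuts, Inf)
    p <- exp(interval_log_prob(mu, sigma, bounds[-length(bounds)], bounds[-1]))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("invalid intervals and scales are rejected", {
  expect_error(interval_log_prob(0, 1, 5, 5), "lo < hi")
  expect_error(interval_log_prob(0, 1, 6, 5), "lo < hi")
  expect_error(interval_log_prob(0, 0, 1, 2), "sigma")
})

test_that("the three-fly worked vial reproduces the hand-computed log-likelihood", {
  vt <- vial_table(make_vial_rows("V1", boundaries = c(90, 100, 110),
                                  deaths = c(0, 1, 1), n_censored = 1))
  ll <- dataset_log_likelihood(
    beta = c(Intercept = 100), sigmas = list(resid = 10),
    group_effects = list(), records = vt, spec = toy_spec()
  )
  manual <- 2 * log(interval_prob_oracle(100, 10, 90, 100)) +
    log(interval_prob_oracle(100, 10, 110, Inf))
  expect_equal(ll, manual, tolerance = 1e-9)
  expect_equal(ll, -3.991, tolerance = 1e-3)
})

test_that("the log-likelihood is linear in the counts", {
  vt <- toy_vial_table()
  df <- as.data.frame(vt)
  df$deaths <- df$deaths * 2L
  last <- !is.na(df$n_censored)
  df$n_censored[last] <- df$n_censored[last] * 2L
  df$n_start <- df$n_start * 2L
  vt2 <- vial_table(df)
  args <- list(beta = c(Intercept = 55), sigmas = list(resid = 12),
               group_effects = list(), spec = toy_spec())
  ll1 <- do.call(dataset_log_likelihood, c(args, list(records = vt)))
  ll2 <- do.call(dataset_log_likelihood, c(args, list(records = vt2)))
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("vial counts equal a brute-force per-fly product on small instances", {
  set.seed(7)
  for (rep in 1:5) {
    mu <- runif(1, 20, 90); sigma <- runif(1, 5, 30)
    # keep boundaries within ~3 SD so the CDF-difference oracle is exact
    boundaries <- sort(runif(4, max(mu - 3 * sigma, 1), mu + 3 * sigma))
    deaths <- as.integer(rmultinom(1, sample(5:20, 1), prob = rep(1, 5)))
    vt <- vial_table(make_vial_rows("V1", boundaries, deaths[1:4], deaths[5]))
    ll <- dataset_log_likelihood(c(Intercept = mu), list(resid = sigma),
                                 list(), vt, toy_spec())
    # brute force: each fly contributes its own interval term via the oracle
    lo <- c(-Inf, boundaries)
    hi <- c(boundaries, Inf)
    per_fly <- unlist(lapply(seq_along(deaths), function(i) {
      rep(log(interval_prob_oracle(mu, sigma, lo[i], hi[i])), deaths[i])
    }))
    expect_equal(ll, sum(per_fly), tolerance = 1e-9)
  }
})

test_that("splitting counts proportionally to model probabilities never raises the log-likelihood", {
  set.seed(8)
  for (i in 1:20) {
    mu <- runif(1, 0, 100); sigma <- runif(1, 2, 30)
    a <- runif(1, mu - 3 * sigma, mu + 3 * sigma)
    b <- a + runif(1, 0.5, 20); cc <- b + runif(1, 0.5, 20)
    p1 <- exp(interval_log_prob(mu, sigma, a, b))
    p2 <- exp(interval_log_prob(mu, sigma, b, cc))
    n <- 10
    c1 <- n * p1 / (p1 + p2); c2 <- n * p2 / (p1 + p2)
    split_ll <- c1 * log(p1) + c2 * log(p2)
    merged_ll <- n * interval_log_prob(mu, sigma, a, cc)
    expect_gte(merged_ll, split_ll - 1e-10)
  }
})

test_that("the log posterior is the sum of its parts on a two-vial toy", {
  vt <- toy_vial_table()
  spec <- model_spec("toy", fixed = character(0), random = c("line", "vial"),
                     priors = list(beta_scale = 100, sigma_scale = 50))
  params <- list(
    beta = c(Intercept = 55), sigma_resid = 12,
    sigma_line = 2, u_line = c(L01 = 0.7),
    sigma_vial = 3, u_vial = c(V1 = -1.2, V2 = 2.1)
  )
  lp <- log_posterior(params, vt, spec)
  ll <- dataset_log_likelihood(params$beta, list(resid = 12),
                               list(line = params$u_line, vial = params$u_vial),
                               vt, spec)
  manual <- ll +
    dnorm(55, 0, 100, log = TRUE) +
    log(2) + dnorm(12, 0, 50, log = TRUE) +
    log(2) + dnorm(2, 0, 50, log = TRUE) +
    dnorm(0.7, 0, 2, log = TRUE) +
    log(2) + dnorm(3, 0, 50, log = TRUE) +
    sum(dnorm(c(-1.2, 2.1), 0, 3, log = TRUE))
  expect_equal(lp, manual, tolerance = 1e-10)
})

test_that("a zero-count dataset contributes prior mass only", {
  vt <- vial_table(make_vial_rows("V1", c(24, 48), c(0L, 0L), 0L))
  spec <- toy_spec()
  lp <- log_posterior(list(beta = c(Intercept = 10), sigma_resid = 5), vt, spec)
  manual <- dnorm(10, 0, 100, log = TRUE) + log(2) + dnorm(5, 0, 50, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)
})

test_that("missing group effects are reported", {
  vt <- toy_vial_table()
  spec <- model_spec("toy", fixed = character(0), random = c("line", "vial"),
                     priors = list(beta_scale = 100, sigma_scale = 50))
  expect_error(
    dataset_log_likelihood(c(Intercept = 50), list(resid = 10),
                           list(line = c(L99 = 1), vial = c(V1 = 0, V2 = 0)),
                           vt, spec),
    "one value per line"
  )
})

test_that("the compiled posterior matches the reference implementation, value and gradient", {
  sim <- simulate_survival_experiment(small_sim_params(seed = 21))
  spec <- model_spec("s", fixed = c("Sex", "Cue"), random = c("line", "vial"),
                     priors = list(beta_scale = 200, sigma_scale = 25))
  ld <- icmix:::prepare_likelihood_data(sim$records, spec)
  pr <- icmix:::resolved_prior_scales(spec, sim$records)
  p <- length(ld$term_names); L <- ld$n_line; V <- ld$n_vial
  set.seed(22)
  theta <- c(rnorm(p, c(60, 0, 0), 2), log(10), log(2), log(3),
             rnorm(L + V, 0, 0.7))
  cpp <- icmix:::.icmix_logpost_grad(
    theta, ld$X, ld$vial_of_row - 1L, ld$lo, ld$hi, ld$w,
    ld$line_of_vial - 1L, ld$n_line, TRUE, TRUE,
    rep(pr$beta_scale, p), pr$sigma_scale
  )
  s_line <- exp(theta[p + 2]); s_vial <- exp(theta[p + 3])
  params <- list(
    beta = theta[1:p], sigma_resid = exp(theta[p + 1]),
    sigma_line = s_line,
    u_line = setNames(s_line * theta[(p + 4):(p + 3 + L)], ld$line_levels),
    sigma_vial = s_vial,
    u_vial = setNames(s_vial * theta[(p + 4 + L):(p + 3 + L + V)], ld$vial_ids)
  )
  # the compiled version works on z and log-sigma: the densities differ by the
  # change-of-variable terms  sum(log sigma) per group + log sigma per SD
  lp_r <- log_posterior(params, sim$records, spec)
  expect_equal(cpp$lp,
               lp_r + L * log(s_line) + V * log(s_vial) +  # z vs u densities
                 theta[p + 1] + theta[p + 2] + theta[p + 3],  # log-sigma Jacobians
               tolerance = 1e-8)

  # gradient against central finite differences on a spread of coordinates
  f <- function(tt) icmix:::.icmix_logpost_grad(
    tt, ld$X, ld$vial_of_row - 1L, ld$lo, ld$hi, ld$w,
    ld$line_of_vial - 1L, ld$n_line, TRUE, TRUE,
    rep(pr$beta_scale, p), pr$sigma_scale
  )$lp
  for (i in c(1, 2, p, p + 1, p + 2, p + 3, p + 5, p + 3 + L + 3)) {
    h <- 1e-5
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    expect_equal(cpp$grad[i], (f(tp) - f(tm)) / (2 * h), tolerance = 1e-4)
  }
})
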