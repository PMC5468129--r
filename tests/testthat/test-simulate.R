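# Synthetic-experiment generators

test_that("deaths plus censored equals the starting count in every vial", {
  for (seed in c(1, 17, 23)) {
    sim <- simulate_survival_experiment(small_sim_params(seed = seed))
    recs <- as_vial_records(sim$records)
    for (r in recs) expect_equal(sum(r$deaths) + r$n_censored, r$n_start)
  }
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  a <- simulate_survival_experiment(small_sim_params(seed = 4))
  b <- simulate_survival_experiment(small_sim_params(seed = 4))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$u_vial, b$truth$u_vial)
  c <- simulate_survival_experiment(small_sim_params(seed = 5))
  expect_false(identical(a$records, c$records))
})

test_that("with all noise at zero, every death falls in the interval holding the mean", {
  params <- survival_sim_params(
    beta = c(Intercept = 50), terms = character(0),
    sigma_resid = 1e-9, sigma_line = 0, sigma_vial = 0,
    vials_per_cell = 1, flies_per_vial = c(5, 5),
    schedule = list(pooled = schedule_spec(4, 12, 96)),
    age_range = c(0, 0), seed = 2
  )
  design <- data.frame(regime = "R", sex = not_applicable(),
                       cue = not_applicable(), starv = not_applicable())
  sim <- simulate_survival_experiment(params, design)
  df <- as.data.frame(sim$records)
  hit <- df$deaths > 0
  expect_true(all(df$interval_lo_h[hit] < 50 & df$interval_hi_h[hit] >= 50))
  expect_equal(sum(df$n_censored, na.rm = TRUE), 0)
})

test_that("interval frequencies converge to the normal-CDF oracle", {
  params <- survival_sim_params(
    beta = c(Intercept = 60), terms = character(0),
    sigma_resid = 10, sigma_line = 0, sigma_vial = 0,
    vials_per_cell = 60, flies_per_vial = c(40, 40),
    schedule = list(pooled = schedule_spec(6, 12, 96)),
    age_range = c(0, 0), n_lines_per_regime = 1, seed = 8
  )
  design <- data.frame(regime = "R", sex = not_applicable(),
                       cue = not_applicable(), starv = not_applicable())
  sim <- simulate_survival_experiment(params, design)
  df <- as.data.frame(sim$records)
  n <- sum(unique(df[, c("vial_id", "n_start")])$n_start)
  for (t in c(48, 60, 72, 96)) {
    frac_dead <- sum(df$deaths[df$interval_hi_h <= t]) / n
    p <- interval_prob_oracle(60, 10, -Inf, t)
    mc <- sqrt(p * (1 - p) / n)
    expect_lt(abs(frac_dead - p), 4 * mc + 1e-12)
  }
})

test_that("egg counts are non-negative integers with the stated mean in the Poisson limit", {
  p <- count_sim_params(beta = c(Intercept = 2.97), dispersion = 1e6,
                        sigma_line = 0, females_per_cell = 10, seed = 3)
  sim <- simulate_fecundity(p, age_classes = "early_4d")
  eggs <- sim$records$eggs
  expect_true(all(eggs >= 0), all(eggs == round(eggs)))
  mu <- exp(2.97)
  se <- sqrt(mu / length(eggs))
  expect_lt(abs(mean(eggs) - mu), 4 * se)
})

test_that("small dispersion produces variance above the mean", {
  p <- count_sim_params(beta = c(Intercept = 2.97), dispersion = 1,
                        sigma_line = 0, females_per_cell = 10, seed = 3)
  sim <- simulate_fecundity(p, age_classes = "early_4d")
  expect_gt(var(sim$records$eggs), mean(sim$records$eggs))
})

test_that("line traits hit cell means exactly at zero noise, with 36 records per trait", {
  cm <- expand.grid(trait = c("glycogen", "TAG"), regime = c("R", "U", "C"),
                    sex = c("F", "M"), stringsAsFactors = FALSE)
  cm$mean <- seq_len(nrow(cm))
  lt <- simulate_line_traits(cm, sigma_between_line = 0, seed = 1)
  df <- as.data.frame(lt$records)
  expect_equal(nrow(df), 72L)  # 18 lines x 2 sexes x 2 traits
  expect_equal(sum(df$trait == "glycogen"), 36L)
  merged <- merge(df, cm, by = c("trait", "regime", "sex"))
  expect_equal(merged$value, merged$mean)
})

test_that("the spread across many lines recovers the between-line SD", {
  cm <- data.frame(trait = "TAG", regime = c("R", "U", "C"), sex = "F",
                   mean = 0)
  lt <- simulate_line_traits(cm, sigma_between_line = 2,
                             n_lines_per_regime = 300, seed = 6)
  s <- sd(lt$records$value)
  expect_lt(abs(s - 2), 4 * 2 / sqrt(2 * 900))  # SE(sd) ~ sigma/sqrt(2n)
})

test_that("the default generating configuration matches the published scale", {
  p <- paperlike_default_params()
  expect_equal(unname(p$beta["Intercept"]), 104.64)
  expect_equal(unname(p$beta["SexM"]), -25.80)
  expect_equal(unname(p$beta[c("SelU", "SelC", "CueCs", "SelC:CueCs")]),
               c(-3.89, -17.92, -7.56, 3.58))
  # implied male reference-regime mean from the printed effects
  expect_equal(unname(p$beta["Intercept"] + p$beta["SexM"]), 78.84)

  sim <- simulate_survival_experiment(p)
  vs <- unique(as.data.frame(sim$records)[, c("vial_id", "sex", "n_start")])
  expect_equal(nrow(vs), 432L)                    # ~220 F + ~215 M vials
  expect_true(all(vs$n_start >= 17 & vs$n_start <= 22))
  # assay ends calibrated to roughly 50% mortality overall
  dead <- sum(sim$records$deaths)
  total <- sum(vs$n_start)
  expect_gt(dead / total, 0.35)
  expect_lt(dead / total, 0.65)
})

test_that("coefficients that do not resolve on the design are an error", {
  p <- small_sim_params()
  p$beta <- c(Intercept = 60, NoSuchTerm = 1)
  expect_error(simulate_survival_experiment(p), "NoSuchTerm")
})
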