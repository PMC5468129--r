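# Fecundity NB mixed model, egg-to-adult binomial GLMM, physiology LMM

test_that("the NB fit recovers a pure-intercept simulation near its generating mean", {
  sim <- simulate_fecundity(count_sim_params(beta = c(Intercept = 2.97),
                                             dispersion = 5, sigma_line = 0.1,
                                             females_per_cell = 5, seed = 2),
                            age_classes = c("early_4d", "early_7d"))
  fit <- fit_negbin_glmm(sim$records)
  ic <- fit$coefficients[fit$coefficients$term == "Intercept", ]
  expect_lt(abs(ic$estimate - 2.97), 0.25)
  expect_equal(exp(2.97), 19.49, tolerance = 1e-3)  # implied egg count scale
  expect_gt(fit$dispersion, 0)
})

test_that("in the Poisson limit the NB dispersion blows up and estimates match Poisson", {
  sim <- simulate_fecundity(count_sim_params(beta = c(Intercept = 2.5),
                                             dispersion = 1e6, sigma_line = 0.05,
                                             females_per_cell = 6, seed = 3),
                            age_classes = "early_4d")
  fit <- fit_negbin_glmm(sim$records)
  expect_gt(fit$dispersion, 50)
  pois <- glmmTMB::glmmTMB(
    eggs ~ 1 + (1 | line_id),
    data = as.data.frame(sim$records), family = stats::poisson()
  )
  ic <- fit$coefficients[fit$coefficients$term == "Intercept", "estimate"]
  expect_equal(ic, unname(glmmTMB::fixef(pois)$cond["(Intercept)"]),
               tolerance = 0.02)
})

test_that("count fits are invariant to record order", {
  sim <- simulate_fecundity(paperlike_fecundity_params("midlife", seed = 5))
  fit1 <- fit_negbin_glmm(sim$records)
  shuffled <- sim$records[rev(seq_len(nrow(sim$records))), ]
  fit2 <- fit_negbin_glmm(fecundity_table(shuffled))
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-5)

  ec <- simulate_eclosion(beta = c(Intercept = 1), seed = 5)
  b1 <- fit_binomial_glmm(ec$records)
  b2 <- fit_binomial_glmm(ec$records[sample(nrow(ec$records)), ])
  expect_equal(b1$coefficients$estimate, b2$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("all-zero treatment cells warn but the NB fit proceeds", {
  sim <- simulate_fecundity(count_sim_params(beta = c(Intercept = 2),
                                             dispersion = 5, sigma_line = 0,
                                             females_per_cell = 3, seed = 7),
                            age_classes = "early_4d")
  df <- as.data.frame(sim$records)
  df$eggs[df$cue == "cold_shock" & df$starv == "starved"] <- 0L
  expect_warning(fit <- fit_negbin_glmm(fecundity_table(df)), "all-zero")
  expect_true(is.finite(fit$coefficients$estimate[1]))
})

test_that("a zero logit intercept recovers survival one-half", {
  ec <- simulate_eclosion(beta = c(Intercept = 0), sigma_line = 0.1,
                          vials_per_cell = 6, eggs_per_vial = 12, seed = 4)
  fit <- fit_binomial_glmm(ec$records)
  ic <- fit$coefficients[fit$coefficients$term == "Intercept", "estimate"]
  expect_lt(abs(stats::plogis(ic) - 0.5), 0.05)
})

test_that("all-success data are flagged as separated, zero-trial vials excluded", {
  ec <- simulate_eclosion(beta = c(Intercept = 2), sigma_line = 0, seed = 6)
  df <- ec$records
  df$n_eclosed <- df$n_eggs
  df$n_eggs[1] <- 0L; df$n_eclosed[1] <- 0L
  fit <- suppressWarnings(suppressMessages(fit_binomial_glmm(df)))
  expect_true(any(grepl("separation", fit$notes)))
  expect_true(any(grepl("zero-trial", fit$notes)))
  ic <- fit$coefficients[fit$coefficients$term == "Intercept", "estimate"]
  expect_gt(stats::plogis(ic), 0.95)
})

test_that("successes above trials are rejected", {
  ec <- simulate_eclosion(beta = c(Intercept = 0), seed = 1)
  df <- ec$records
  df$n_eclosed[1] <- df$n_eggs[1] + 1L
  expect_error(fit_binomial_glmm(df), "exceed trials")
})

test_that("the physiology LMM reproduces cell means exactly on noise-free data", {
  cm <- expand.grid(trait = "dry_weight", regime = c("R", "U", "C"),
                    sex = c("F", "M"), stringsAsFactors = FALSE)
  cm$mean <- 5
  lt <- simulate_line_traits(cm, sigma_between_line = 0, seed = 1)
  fit <- fit_gaussian_lmm(lt$records)
  est <- fit$coefficients
  expect_equal(est[est$term == "Intercept", "estimate"], 5, tolerance = 1e-8)
  others <- est[est$term != "Intercept", "estimate"]
  expect_equal(unname(others), rep(0, length(others)), tolerance = 1e-8)
})

test_that("with no line variance the LMM agrees with the classical two-way ANOVA", {
  cm <- expand.grid(trait = "feeding", regime = c("R", "U", "C"),
                    sex = c("F", "M"), stringsAsFactors = FALSE)
  cm$mean <- c(10, 10, 8, 9, 9, 7)  # a selection effect of +2 on R and U
  lt <- simulate_line_traits(cm, sigma_between_line = 0, sigma_within = 0.6,
                             seed = 9)
  fit <- fit_gaussian_lmm(lt$records)
  df <- icmix:::term_data_for_fit(as.data.frame(lt$records),
                                  model_spec("t", fixed = c("Sel", "Sex", "Sel:Sex"),
                                             reference = list(Sel = "C", Sex = "F")))
  anova_fit <- stats::lm(value ~ Sel + Sex + Sel:Sex, data = df)
  lmm_est <- fit$coefficients$estimate
  lm_est <- unname(stats::coef(anova_fit))
  expect_equal(lmm_est, lm_est, tolerance = 0.05)
})

test_that("the variance decomposition matches the generating moments on balanced data", {
  cm <- data.frame(trait = "trehalose", regime = c("R", "U", "C"), sex = "F",
                   mean = 0)
  cm <- rbind(cm, transform(cm, sex = "M"))
  lt <- simulate_line_traits(cm, sigma_between_line = 1.5, sigma_within = 0.8,
                             n_lines_per_regime = 60, seed = 13)
  fit <- fit_gaussian_lmm(lt$records)
  expect_equal(unname(fit$ranef_sd["line"]), 1.5, tolerance = 0.25)
  expect_equal(fit$resid_sd, 0.8, tolerance = 0.15)
  total <- var(lt$records$value)
  expect_equal(unname(fit$ranef_sd["line"])^2 + fit$resid_sd^2, total,
               tolerance = 0.3)
})

test_that("traits observed in fewer than two lines per regime are refused", {
  cm <- data.frame(trait = "TAG", regime = c("R", "U", "C"), sex = "F", mean = 1)
  lt <- simulate_line_traits(cm, 0.1, n_lines_per_regime = 1, seed = 1)
  expect_error(fit_gaussian_lmm(lt$records), "fewer than 2 lines")
  multi <- rbind(lt$records,
                 transform(lt$records, trait = "glycogen"))
  expect_error(fit_gaussian_lmm(line_trait_table(multi)), "one trait at a time")
})
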