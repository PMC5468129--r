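# Data model and CSV round trips

test_that("a minimal two-interval file reads into one validated record", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_vial_rows("V1", boundaries = c(24, 48), deaths = c(1, 1),
                       n_censored = 1)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  vt <- read_vial_table(path)
  recs <- as_vial_records(vt)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$boundaries, c(24, 48))
  expect_equal(recs[[1]]$n_start, 3L)
})

test_that("count mismatches are rejected with the vial named", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_vial_rows("V1", boundaries = c(24, 48), deaths = c(1, 1),
                       n_censored = 2)
  df$n_start <- 3L  # file claims 3 flies but 1+1+2 = 4
  utils::write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_vial_table(path), "counts do not sum to n_start")
  expect_error(read_vial_table(path), "V1")
})

test_that("write then read is the identity on simulated datasets", {
  sim <- simulate_survival_experiment(small_sim_params(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_vial_table(sim$records, path)
  back <- read_vial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               ignore_attr = TRUE, tolerance = 1e-12)

  fec <- simulate_fecundity(paperlike_fecundity_params("early", seed = 11))
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_fecundity_table(fec$records, fpath)
  expect_equal(as.data.frame(read_fecundity_table(fpath)),
               as.data.frame(fec$records), ignore_attr = TRUE)

  cm <- data.frame(trait = "TAG", regime = c("R", "U", "C"), sex = "F",
                   mean = c(1, 2, 3))
  lt <- simulate_line_traits(cm, 0.5, seed = 11)
  lpath <- withr::local_tempfile(fileext = ".csv")
  write_line_trait_table(lt$records, lpath)
  expect_equal(as.data.frame(read_line_trait_table(lpath)),
               as.data.frame(lt$records), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("an empty record set writes a header-only file; 3 intervals give 3 rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_vial_table(data.frame(), path)
  expect_length(readLines(path), 1L)

  path2 <- withr::local_tempfile(fileext = ".csv")
  one <- vial_table(make_vial_rows("V1", c(10, 20, 30), c(1, 0, 2), 0))
  write_vial_table(one, path2)
  expect_length(readLines(path2), 4L)  # header + 3 interval rows
})

test_that("validation flags every constructed violation and nothing on valid data", {
  sim <- simulate_survival_experiment(small_sim_params(seed = 3))
  expect_equal(nrow(validate_dataset(sim$records)), 0L)

  corruptions <- list(
    negative_deaths = function(df) { df$deaths[2] <- -1L; df },
    bad_boundaries = function(df) { df$interval_hi_h[2] <- df$interval_lo_h[2]; df },
    count_mismatch = function(df) {
      last <- which(!is.na(df$n_censored))[1]
      df$n_censored[last] <- df$n_censored[last] + 1L
      df
    },
    misplaced_censored = function(df) { df$n_censored[1] <- 0L; df },
    bad_regime = function(df) { df$regime[1] <- "X"; df },
    duplicate_vial_id = function(df) {
      k <- sum(df$vial_id == df$vial_id[1])
      df$vial_id[nrow(df) - seq_len(k) + 1L] <- df$vial_id[1]
      df
    }
  )
  base <- as.data.frame(sim$records)
  for (rule in names(corruptions)) {
    rep <- validate_dataset(corruptions[[rule]](base))
    expect_gt(nrow(rep), 0, label = paste("violations for", rule))
    expect_true(rule %in% rep$rule, label = paste("rule flagged:", rule))
  }
})

test_that("vial records and tables convert back and forth", {
  sim <- simulate_survival_experiment(small_sim_params(seed = 9))
  recs <- as_vial_records(sim$records)
  back <- vial_records_to_table(recs)
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a column-mapping schema adapts foreign layouts", {
  sim <- simulate_survival_experiment(small_sim_params(seed = 5))
  df <- as.data.frame(sim$records)
  names(df)[names(df) == "vial_id"] <- "Vial"
  names(df)[names(df) == "deaths"] <- "n_dead"
  df$sex <- c(F = "female", M = "male")[df$sex]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")

  sch <- table_schema(columns = c(vial_id = "Vial", deaths = "n_dead"),
                      levels = list(sex = c(F = "female", M = "male")))
  back <- read_vial_table(path, schema = sch)
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               ignore_attr = TRUE, tolerance = 1e-12)

  bad <- table_schema(columns = c(vial_id = "NoSuchColumn"))
  expect_error(read_vial_table(path, schema = bad), "NoSuchColumn")
})
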