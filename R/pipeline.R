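# Orchestration: simulate -> fit -> summarize -> report, driven by a config
# list (or YAML file), with a JSON manifest per run; and the
# parameter-recovery harness used to validate the estimators.

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order inside `out_dir`, writing CSV
#' outputs, an effect table per fit, and a machine-readable `manifest.json`
#' (stages, seeds, input/output files with MD5 hashes). Supported stages:
#' \describe{
#'   \item{simulate}{`type: simulate`; `params: paperlike | devtime` or an
#'     explicit [survival_sim_params()] field list; writes `<name>.csv`.}
#'   \item{fit}{`type: fit`; `input`: a vial CSV (or the name of an earlier
#'     simulate stage); `spec`: [model_spec()] fields; `sampler`: chains /
#'     warmup / iter; writes `<name>_summary.csv` and `<name>_table.txt`.}
#'   \item{recover}{`type: recover`; `params`, `spec`, `n_replicates`;
#'     writes `<name>_recovery.csv`.}
#' }
#' Any stage failure aborts with an error naming the stage; outputs of
#' completed stages are retained.
#'
#' @param config list or path to a YAML file: fields `seed`, `out_dir`,
#'   `stages` (named list of stage configs).
#' @return the run directory, invisibly; the manifest describes all outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = seed, package_version = as.character(
    utils::packageVersion("icmix")), stages = list())
  datasets <- list()

  for (name in names(config$stages)) {
    st <- config$stages[[name]]
    entry <- tryCatch(
      switch(st$type %||% stop("stage type missing"),
        simulate = stage_simulate(st, name, seed, out_dir, datasets),
        fit = stage_fit(st, name, seed, out_dir, datasets),
        recover = stage_recover(st, name, seed, out_dir),
        stop("unknown stage type '", st$type, "'")
      ),
      error = function(e) {
        write_manifest(manifest, out_dir)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    datasets <- entry$datasets %||% datasets
    manifest$stages[[name]] <- entry$manifest
  }
  write_manifest(manifest, out_dir)
  invisible(out_dir)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

file_entry <- function(path) {
  list(path = path, md5 = unname(tools::md5sum(path)))
}

sim_params_from_config <- function(cfg, seed) {
  if (is.character(cfg)) {
    return(switch(cfg,
      paperlike = paperlike_default_params(seed = seed),
      devtime = paperlike_devtime_params(seed = seed),
      stop("unknown params preset '", cfg, "'")
    ))
  }
  cfg$seed <- cfg$seed %||% seed
  if (!is.null(cfg$schedule)) {
    cfg$schedule <- lapply(cfg$schedule, function(s)
      schedule_spec(s$day_spacing_h, s$overnight_gap_h, s$end_h))
  }
  if (!is.null(cfg$beta)) cfg$beta <- unlist(cfg$beta)
  do.call(survival_sim_params, cfg)
}

spec_from_config <- function(cfg) {
  args <- list(response = cfg$response %||% "trait")
  for (f in c("fixed", "random", "family")) {
    if (!is.null(cfg[[f]])) args[[f]] <- unlist(cfg[[f]])
  }
  if (!is.null(cfg$reference)) args$reference <- as.list(cfg$reference)
  if (!is.null(cfg$age_covariate)) args$age_covariate <- isTRUE(cfg$age_covariate)
  if (!is.null(cfg$priors)) args$priors <- cfg$priors
  do.call(model_spec, args)
}

stage_simulate <- function(st, name, seed, out_dir, datasets) {
  params <- sim_params_from_config(st$params %||% "paperlike",
                                   seed = st$seed %||% seed)
  sim <- simulate_survival_experiment(params)
  path <- file.path(out_dir, paste0(name, ".csv"))
  write_vial_table(sim$records, path)
  datasets[[name]] <- sim
  list(datasets = datasets,
       manifest = list(type = "simulate", seed = params$seed,
                       n_vials = length(unique(sim$records$vial_id)),
                       output = file_entry(path)))
}

stage_fit <- function(st, name, seed, out_dir, datasets) {
  input <- st$input %||% stop("fit stage needs an 'input'")
  if (!is.null(datasets[[input]])) {
    records <- datasets[[input]]$records
    input_desc <- paste0("stage:", input)
  } else {
    if (!file.exists(input)) stop("input path does not exist: ", input)
    records <- read_vial_table(input)
    input_desc <- input
  }
  spec <- spec_from_config(st$spec %||% list())
  sampler <- st$sampler %||% list()
  fit <- fit_mcmc(records, spec,
                  chains = sampler$chains %||% 2L,
                  warmup = sampler$warmup %||% 400L,
                  iter = sampler$iter %||% 400L,
                  seed = st$seed %||% seed)
  summ <- summarize(fit)
  core <- summ[summ$term %in% c(fit$term_names, "sigma_resid", "sigma_line",
                                "sigma_vial"), , drop = FALSE]
  csv_path <- file.path(out_dir, paste0(name, "_summary.csv"))
  utils::write.csv(core, csv_path, row.names = FALSE)
  txt_path <- file.path(out_dir, paste0(name, "_table.txt"))
  tbl <- render_effect_table(core, path = txt_path)
  list(manifest = list(
    type = "fit", input = input_desc, seed = st$seed %||% seed,
    sampler = list(chains = fit$chains, warmup = fit$warmup, iter = fit$iter),
    convergence_warnings = fit$warnings,
    outputs = list(file_entry(csv_path), file_entry(txt_path))
  ))
}

stage_recover <- function(st, name, seed, out_dir) {
  params <- sim_params_from_config(st$params %||% "paperlike",
                                   seed = st$seed %||% seed)
  spec <- spec_from_config(st$spec %||% list())
  rep <- recovery_study(params, spec,
                        n_replicates = st$n_replicates %||% 5L,
                        seed = st$seed %||% seed,
                        sampler = st$sampler %||% list())
  path <- file.path(out_dir, paste0(name, "_recovery.csv"))
  utils::write.csv(rep$parameters, path, row.names = FALSE)
  list(manifest = list(type = "recover", seed = st$seed %||% seed,
                       n_replicates = rep$n_replicates,
                       runtime_s = rep$runtime_s,
                       output = file_entry(path)))
}

#' Parameter-recovery study for the interval-censored model
#'
#' Simulates `n_replicates` experiments from `sim_params`, fits each with
#' [fit_mcmc()] under `spec`, and aggregates per-parameter coverage of the
#' 95% credible interval, bias and RMSE of the posterior mean against the
#' generating values (fitted terms absent from the generator have truth 0).
#' Replicates with convergence warnings are flagged, not dropped.
#'
#' @param sim_params a [survival_sim_params()].
#' @param spec the [model_spec()] to fit.
#' @param n_replicates number of simulated experiments (>= 1).
#' @param seed integer; replicate r uses a seed derived from `seed` and `r`.
#' @param sampler list: chains, warmup, iter (defaults 2 / 400 / 400).
#' @return list of class `recovery_report`: `parameters` (data.frame with
#'   truth, mean posterior mean, coverage, bias, rmse, mean CI width),
#'   `n_replicates`, `flagged` (replicates with warnings), `runtime_s`.
#' @export
recovery_study <- function(sim_params, spec, n_replicates, seed = 1L,
                           sampler = list()) {
  stopifnot(n_replicates >= 1)
  t0 <- Sys.time()
  chains <- sampler$chains %||% 2L
  warmup <- sampler$warmup %||% 400L
  iter <- sampler$iter %||% 400L

  rows <- list()
  flagged <- integer()
  for (r in seq_len(n_replicates)) {
    rep_seed <- (as.integer(seed) + r * 104729L) %% 2147483647L
    params_r <- sim_params
    params_r$seed <- rep_seed
    sim <- simulate_survival_experiment(params_r)
    fit <- withCallingHandlers(
      fit_mcmc(sim$records, spec, chains = chains, warmup = warmup,
               iter = iter, seed = rep_seed),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(fit$warnings) > 0L) flagged <- c(flagged, r)
    summ <- summarize(fit)

    truth_beta <- sim$truth$beta
    track <- c(fit$term_names, "sigma_resid",
               if ("line" %in% spec$random) "sigma_line",
               if ("vial" %in% spec$random) "sigma_vial")
    truth <- vapply(track, function(tm) {
      if (tm %in% names(truth_beta)) truth_beta[[tm]]
      else switch(tm, sigma_resid = sim$truth$sigma_resid,
                  sigma_line = sim$truth$sigma_line,
                  sigma_vial = sim$truth$sigma_vial,
                  age_c = sim$truth$age_slope, 0)
    }, numeric(1))
    s <- summ[match(track, summ$term), , drop = FALSE]
    rows[[r]] <- data.frame(
      replicate = r, term = track, truth = unname(truth),
      post_mean = s$mean, ci_low = s$ci_low, ci_high = s$ci_high,
      covered = s$ci_low <= truth & truth <= s$ci_high,
      flagged = length(fit$warnings) > 0L,
      stringsAsFactors = FALSE
    )
  }
  all_rows <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(all_rows, all_rows$term), function(g) {
    data.frame(
      term = g$term[1], truth = g$truth[1],
      mean_post_mean = mean(g$post_mean),
      coverage = mean(g$covered),
      n_covered = sum(g$covered),
      bias = mean(g$post_mean - g$truth),
      rmse = sqrt(mean((g$post_mean - g$truth)^2)),
      mean_ci_width = mean(g$ci_high - g$ci_low),
      stringsAsFactors = FALSE
    )
  }))
  agg <- agg[match(unique(all_rows$term), agg$term), ]
  rownames(agg) <- NULL
  structure(
    list(parameters = agg, replicates = all_rows,
         n_replicates = n_replicates, flagged = flagged,
         runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates, %.1f s", x$n_replicates,
              x$runtime_s))
  if (length(x$flagged) > 0L) {
    cat(sprintf(" (%d flagged: %s)", length(x$flagged),
                paste(x$flagged, collapse = ",")))
  }
  cat("\n")
  print(x$parameters, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Render an ordered effect table
#'
#' Orders rows as published effect tables do -- intercept first, then main
#' effects, then interactions -- marks significance, and optionally filters to
#' significant rows only (the style in which only statistically supported
#' effects are printed).
#'
#' @param summary data.frame with `term`, estimate columns (`mean` or
#'   `estimate`), `ci_low`, `ci_high`, `significant`.
#' @param significant_only drop rows whose interval covers zero (variance
#'   components are always kept).
#' @param path optional file; the aligned text table is written there.
#' @return the ordered data.frame (invisibly if `path` given).
#' @export
render_effect_table <- function(summary, significant_only = FALSE, path = NULL) {
  df <- as.data.frame(summary)
  if (!"estimate" %in% names(df) && "mean" %in% names(df)) {
    df$estimate <- df$mean
  }
  df <- df[, intersect(c("term", "estimate", "ci_low", "ci_high", "significant"),
                       names(df)), drop = FALSE]
  is_sigma <- grepl("^sigma_", df$term)
  rank <- ifelse(df$term == "Intercept", 0L,
                 ifelse(is_sigma, 3L,
                        ifelse(grepl(":", df$term, fixed = TRUE), 2L, 1L)))
  df <- df[order(rank, seq_len(nrow(df))), , drop = FALSE]
  if (significant_only) {
    df <- df[df$significant | is_sigma[order(rank, seq_along(rank))], ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  lines <- c(
    sprintf("%-18s %10s %22s", "Effect", "Estimate", "95% C.I."),
    sprintf("%-18s %10.2f %22s", df$term, df$estimate,
            sprintf("(%.2f, %.2f)", df$ci_low, df$ci_high))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(df))
  }
  cat(lines, sep = "\n")
  invisible(df)
}
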