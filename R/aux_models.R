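# Remaining estimation stages: negative-binomial mixed regression for
# fecundity (log link, mean-shape parameterization: variance = mu + mu^2 /
# shape), binomial mixed regression for egg-to-adult survival (logit link),
# and Gaussian linear mixed models for one-measurement-per-line physiology
# traits. Estimation delegates to glmmTMB / lme4; the summary schema is the
# same as for the Bayesian fits (term, estimate, ci_low, ci_high,
# significant), with the method flagged.

term_data_for_fit <- function(records, spec) {
  codes <- factor_codes()
  mains <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  df <- as.data.frame(records)
  out <- df
  for (f in mains) {
    info <- codes[[f]]
    vals <- as.character(df[[info$column]])
    if (any(vals == not_applicable())) {
      stop("factor ", f, " is not_applicable in the data but is a fixed term")
    }
    ref <- spec$reference[[f]]
    lv <- c(ref, setdiff(names(info$levels), ref))
    out[[f]] <- factor(info$levels[vals], levels = info$levels[lv])
  }
  out
}

fixed_formula_rhs <- function(spec) {
  paste(spec$fixed, collapse = " + ")
}

# fixed-effect standard errors, tolerant of degenerate (zero-variance) fits
safe_fixef_se <- function(fit) {
  v <- suppressWarnings(tryCatch(as.matrix(stats::vcov(fit)),
                error = function(e) tryCatch(
                  as.matrix(stats::vcov(fit, use.hessian = FALSE)),
                  error = function(e2) NULL
                )))
  if (is.null(v)) return(rep(0, length(lme4::fixef(fit))))
  sqrt(pmax(diag(v), 0))
}

wald_summary <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = sub("^\\(Intercept\\)$", "Intercept", names(est)),
    estimate = unname(est),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se),
    stringsAsFactors = FALSE
  )
}

finalize_count_summary <- function(tab, dispersion, ranef_sd, method, notes) {
  tab$significant <- tab$ci_low > 0 | tab$ci_high < 0
  structure(
    list(coefficients = tab, dispersion = dispersion, ranef_sd = ranef_sd,
         method = method, notes = notes),
    class = "count_model_summary"
  )
}

#' @export
print.count_model_summary <- function(x, ...) {
  cat(sprintf("<count_model_summary> method %s", x$method))
  if (!is.null(x$dispersion)) cat(sprintf(", dispersion %.3g", x$dispersion))
  cat("\n")
  print(x$coefficients, row.names = FALSE)
  if (length(x$notes) > 0L) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Negative-binomial mixed model for egg counts
#'
#' Log-link negative binomial regression of per-female egg counts with a
#' replicate-line random intercept, fitted by maximum likelihood (glmmTMB,
#' nbinom2: variance = mu + mu^2/shape). The reference cell defaults to
#' regime C without cold shock and without starvation, so the intercept is
#' the log expected egg count of unmanipulated control females. Fit the early
#' (4/7-day) and mid-life (14-day) age blocks separately, as the age classes
#' are distinct assays.
#'
#' @param records a [fecundity_table()].
#' @param spec a [model_spec()] (defaults: Sel + Cue + Starv, reference C).
#' @param level credible/confidence level for the Wald intervals.
#' @return a `count_model_summary`: coefficient table on the log scale,
#'   dispersion (NB shape) estimate, line SD, method flag.
#' @export
fit_negbin_glmm <- function(records,
                            spec = model_spec(
                              "eggs", fixed = c("Sel", "Cue", "Starv"),
                              reference = list(Sel = "C", Cue = "none",
                                               Starv = "none"),
                              random = "line"
                            ),
                            level = 0.95) {
  df <- term_data_for_fit(records, spec)
  if (any(df$eggs < 0) || any(df$eggs != round(df$eggs))) {
    stop("eggs must be non-negative integers")
  }
  if (!"line" %in% spec$random) stop("the fecundity model requires a line random intercept")
  notes <- character()
  cell <- interaction(lapply(intersect(c("Sel", "Cue", "Starv"), names(df)),
                             function(f) df[[f]]))
  zero_cells <- tapply(df$eggs, cell, function(v) all(v == 0))
  if (any(zero_cells, na.rm = TRUE)) {
    notes <- c(notes, "all-zero counts in at least one treatment cell")
    warning("all-zero egg counts in at least one treatment cell; fit proceeds",
            call. = FALSE)
  }
  fml <- stats::as.formula(paste("eggs ~", fixed_formula_rhs(spec), "+ (1 | line_id)"))
  fit <- glmmTMB::glmmTMB(fml, data = df, family = glmmTMB::nbinom2())
  co <- summary(fit)$coefficients$cond
  tab <- wald_summary(co[, "Estimate"], co[, "Std. Error"], level)
  ranef_sd <- sqrt(as.numeric(glmmTMB::VarCorr(fit)$cond$line_id))
  finalize_count_summary(tab, dispersion = stats::sigma(fit),
                         ranef_sd = c(line = ranef_sd),
                         method = "ML (glmmTMB, nbinom2)", notes = notes)
}

#' Binomial mixed model for egg-to-adult survival
#'
#' Logit-link binomial regression of per-vial eclosion successes with a
#' replicate-line random intercept (add `"vial"` to `spec$random` for a vial
#' intercept as an overdispersion term). Zero-trial vials are excluded with a
#' note; complete separation is flagged, not hidden.
#'
#' @param records data.frame with columns `vial_id`, `line_id`, `regime`,
#'   `cue`, `starv`, `n_eggs` (trials) and `n_eclosed` (successes).
#' @param spec a [model_spec()] (defaults: Sel + Cue + Starv, reference C).
#' @param level confidence level.
#' @return a `count_model_summary` on the logit scale (dispersion is `NULL`).
#' @export
fit_binomial_glmm <- function(records,
                              spec = model_spec(
                                "eclosion", fixed = c("Sel", "Cue", "Starv"),
                                reference = list(Sel = "C", Cue = "none",
                                                 Starv = "none"),
                                random = "line"
                              ),
                              level = 0.95) {
  df <- term_data_for_fit(records, spec)
  if (any(df$n_eclosed > df$n_eggs)) stop("successes exceed trials in some vial")
  notes <- character()
  drop0 <- df$n_eggs == 0
  if (any(drop0)) {
    notes <- c(notes, sprintf("excluded %d zero-trial vial(s)", sum(drop0)))
    df <- df[!drop0, , drop = FALSE]
  }
  re <- "(1 | line_id)"
  if ("vial" %in% spec$random) re <- paste(re, "+ (1 | vial_id)")
  fml <- stats::as.formula(paste("cbind(n_eclosed, n_eggs - n_eclosed) ~",
                                 fixed_formula_rhs(spec), "+", re))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = df, family = stats::binomial(),
                control = lme4::glmerControl(
                  check.response.not.const = "ignore"
                ))
  ))
  if (all(df$n_eclosed == df$n_eggs) || all(df$n_eclosed == 0)) {
    notes <- c(notes, "degenerate all-success/all-failure data: separation, estimates diverge")
  }
  est <- lme4::fixef(fit)
  tab <- wald_summary(est, safe_fixef_se(fit), level)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- stats::setNames(vc$sdcor, sub("_id$", "", vc$grp))
  finalize_count_summary(tab, dispersion = NULL, ranef_sd = ranef_sd,
                         method = "ML (lme4::glmer, binomial)", notes = notes)
}

#' Gaussian linear mixed model for per-line physiology traits
#'
#' With one measurement per line and sex, the replicate-line random intercept
#' links a line's two sex measurements, and the residual absorbs the
#' line-by-sex remainder. Fixed effects default to Sel + Sex + Sel:Sex.
#' Refuses to fit a trait observed in fewer than two lines per regime.
#'
#' @param records a [line_trait_table()] restricted to one trait.
#' @param spec a [model_spec()].
#' @param level confidence level.
#' @return list of class `lmm_summary`: coefficient table, `resid_sd`,
#'   `ranef_sd`, method flag.
#' @export
fit_gaussian_lmm <- function(records,
                             spec = model_spec(
                               "trait", fixed = c("Sel", "Sex", "Sel:Sex"),
                               reference = list(Sel = "C", Sex = "F"),
                               random = "line"
                             ),
                             level = 0.95) {
  df <- as.data.frame(records)
  if (length(unique(df$trait)) > 1L) {
    stop("fit one trait at a time (got: ",
         paste(unique(df$trait), collapse = ", "), ")")
  }
  n_lines <- tapply(df$line_id, df$regime, function(x) length(unique(x)))
  if (any(n_lines < 2L, na.rm = TRUE)) {
    stop("refusing to fit: fewer than 2 lines per regime for this trait")
  }
  df <- term_data_for_fit(df, spec)
  fml <- stats::as.formula(paste("value ~", fixed_formula_rhs(spec), "+ (1 | line_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  est <- lme4::fixef(fit)
  tab <- wald_summary(est, safe_fixef_se(fit), level)
  tab$significant <- tab$ci_low > 0 | tab$ci_high < 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  line_sd <- vc$sdcor[vc$grp == "line_id"]
  structure(
    list(coefficients = tab,
         resid_sd = stats::sigma(fit),
         ranef_sd = c(line = line_sd),
         method = "REML (lme4::lmer)"),
    class = "lmm_summary"
  )
}

#' @export
print.lmm_summary <- function(x, ...) {
  cat(sprintf("<lmm_summary> method %s, residual SD %.3g, line SD %.3g\n",
              x$method, x$resid_sd, x$ranef_sd["line"]))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
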