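# Model specification and treatment-coded design matrices. Factor columns in
# the data (regime, sex, cue, starv) map to the model factors Sel, Sex, Cue,
# Starv; coefficient names follow the conventional Sel U / Cue Cs style
# (SelU, SelC, SexM, CueCs, StarvS, SelC:CueCs, ...).

# short level codes used in coefficient names
factor_codes <- function() {
  list(
    Sel   = list(column = "regime", levels = c(R = "R", U = "U", C = "C")),
    Sex   = list(column = "sex",    levels = c(F = "F", M = "M")),
    Cue   = list(column = "cue",    levels = c(none = "", cold_shock = "Cs")),
    Starv = list(column = "starv",  levels = c(none = "", starved = "S"))
  )
}

#' Declare a mixed-model specification
#'
#' Describes one trait's model: the fixed-effect terms over the experimental
#' factors (plus an optional continuous adult-age covariate), the reference
#' level of each factor (the intercept's meaning), which normal random
#' intercepts enter (replicate line, vial), prior scales, and the response
#' family for time-to-event traits.
#'
#' @param response trait name (free text, used in labels).
#' @param fixed character vector of fixed terms over `Sex`, `Sel`, `Cue`,
#'   `Starv`, e.g. `c("Sex", "Sel", "Cue", "Sel:Cue")`. Interactions must be
#'   over included main effects.
#' @param reference named list of reference levels, data labels (e.g.
#'   `list(Sel = "R", Sex = "F", Cue = "none", Starv = "none")`).
#' @param age_covariate include the centered adult-age-at-start covariate
#'   (`age_c`, hours) as a fixed term.
#' @param random character subset of `c("line", "vial")`.
#' @param priors list with `beta_scale` (scalar or per-term vector, prior SD
#'   of coefficients) and `sigma_scale` (scalar or length-3 vector, half-normal
#'   scales for residual/line/vial SDs). `NULL` entries default at fit time to
#'   10x and 1x a crude response SD estimated from event midpoints.
#' @param family `"normal"` models latent event times on the hours scale;
#'   `"lognormal"` models log-hours (a sensitivity switch; boundaries must
#'   then be positive).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("Sex", "Sel", "Cue", "Sel:Cue"),
                       reference = list(Sel = "R", Sex = "F",
                                        Cue = "none", Starv = "none"),
                       age_covariate = FALSE,
                       random = c("line", "vial"),
                       priors = list(beta_scale = NULL, sigma_scale = NULL),
                       family = c("normal", "lognormal")) {
  family <- match.arg(family)
  codes <- factor_codes()
  mains <- unlist(strsplit(fixed, ":", fixed = TRUE))
  unknown <- setdiff(mains, names(codes))
  if (length(unknown) > 0L) {
    stop("unknown model factor(s): ", paste(unknown, collapse = ", "))
  }
  for (tm in fixed[grepl(":", fixed)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% fixed)) {
      stop("interaction '", tm, "' requires its main effects among the fixed terms")
    }
  }
  for (f in unique(mains)) {
    ref <- reference[[f]]
    if (is.null(ref) || !ref %in% names(codes[[f]]$levels)) {
      stop("no valid reference level declared for factor ", f)
    }
  }
  stopifnot(all(random %in% c("line", "vial")))
  structure(list(response = response, fixed = fixed, reference = reference,
                 age_covariate = isTRUE(age_covariate), random = random,
                 priors = priors, family = family),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s latent scale)\n", x$response, x$family))
  cat("  fixed:  ", paste(x$fixed, collapse = " + "),
      if (x$age_covariate) " + age_c" else "", "\n", sep = "")
  cat("  random: ", paste(x$random, collapse = ", "), "\n", sep = "")
  refs <- vapply(names(x$reference), function(f)
    paste0(f, "=", x$reference[[f]]), character(1))
  cat("  reference: ", paste(refs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the treatment-coded design matrix for a specification
#'
#' One row per experimental unit (vial for time-to-event traits). Factors are
#' dummy-coded against the spec's reference levels; the age covariate, when
#' present, is centered at its mean (or at `age_center` when supplied, e.g.
#' for prediction on new data).
#'
#' @param data data.frame with the factor columns `regime`, `sex`, `cue`,
#'   `starv` and, if the spec uses the age covariate, `start_age_h`.
#' @param spec a [model_spec()].
#' @param age_center optional fixed centering value for the age covariate.
#' @return list with `X` (numeric matrix), `term_names`, and `age_center`.
#' @export
build_design_matrix <- function(data, spec, age_center = NULL) {
  codes <- factor_codes()
  mains <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  fac <- list()
  for (f in mains) {
    info <- codes[[f]]
    vals <- as.character(data[[info$column]])
    if (any(vals == not_applicable())) {
      stop("factor ", f, " is marked not_applicable in the data but appears ",
           "in the fixed terms")
    }
    bad <- setdiff(unique(vals), names(info$levels))
    if (length(bad) > 0L) {
      stop("unseen level(s) for factor ", f, ": ", paste(bad, collapse = ", "))
    }
    ref <- spec$reference[[f]]
    lv <- c(ref, setdiff(names(info$levels), ref))
    fac[[f]] <- factor(info$levels[vals], levels = info$levels[lv])
  }
  fac <- if (length(fac) == 0L) {
    data.frame(row.names = seq_len(nrow(data)))
  } else {
    as.data.frame(fac, stringsAsFactors = FALSE)
  }
  rhs <- spec$fixed
  if (spec$age_covariate) {
    if (is.null(data$start_age_h)) stop("age covariate requested but start_age_h absent")
    if (is.null(age_center)) age_center <- mean(data$start_age_h)
    fac$age_c <- data$start_age_h - age_center
    rhs <- c(rhs, "age_c")
  } else {
    age_center <- NA_real_
  }
  fml <- if (length(rhs) == 0L) ~1 else stats::reformulate(rhs)
  X <- stats::model.matrix(fml, data = fac)
  colnames(X)[colnames(X) == "(Intercept)"] <- "Intercept"
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  list(X = X, term_names = colnames(X), age_center = age_center)
}

#' Resolve a named coefficient vector against a design matrix
#'
#' Coefficients named in `beta` must all correspond to design columns; columns
#' without a named coefficient are taken as zero. Used both by the simulator
#' (to inject generating values) and by reporting.
#'
#' @param beta named numeric vector.
#' @param term_names design-matrix column names.
#' @return numeric vector of length `length(term_names)`.
#' @export
resolve_beta <- function(beta, term_names) {
  unresolved <- setdiff(names(beta), term_names)
  if (length(unresolved) > 0L) {
    stop("coefficient name(s) not resolvable on this design: ",
         paste(unresolved, collapse = ", "),
         " (design terms: ", paste(term_names, collapse = ", "), ")")
  }
  out <- stats::setNames(numeric(length(term_names)), term_names)
  out[names(beta)] <- beta
  out
}
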