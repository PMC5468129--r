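# Data model: vial-level interval-censored counts, per-female egg counts,
# per-line physiology values. Canonical containers are validated data.frames
# in the long CSV layout; list-of-record views are provided for convenience.

#' Closed label sets for the experimental factors
#'
#' The selection experiment crosses three selection regimes (R: cold shock
#' reliably precedes starvation; U: cold shock uncorrelated with starvation;
#' C: benign control), two sexes, a cold-shock cue and a starvation treatment.
#' A factor that does not apply to a trait (e.g. sex for egg-to-adult
#' developmental time, where sexes are pooled) is recorded with the designated
#' label `"not_applicable"`, never dropped.
#'
#' @return Named list of character vectors, one per factor.
#' @export
factor_levels <- function() {
  list(
    regime = c("R", "U", "C", "not_applicable"),
    sex    = c("F", "M", "not_applicable"),
    cue    = c("none", "cold_shock", "not_applicable"),
    starv  = c("none", "starved", "not_applicable")
  )
}

#' @rdname factor_levels
#' @export
not_applicable <- function() "not_applicable"

age_class_levels <- function() c("early_4d", "early_7d", "midlife_14d")

trait_levels <- function() {
  c("feeding", "dry_weight", "wet_weight", "water_pct", "glycogen",
    "TAG", "body_glucose", "hemolymph_glucose", "trehalose")
}

vial_table_columns <- function() {
  c("vial_id", "line_id", "regime", "sex", "cue", "starv",
    "start_age_h", "n_start", "interval_lo_h", "interval_hi_h",
    "deaths", "n_censored")
}

fecundity_table_columns <- function() {
  c("female_id", "line_id", "regime", "cue", "starv", "age_class", "eggs")
}

line_trait_table_columns <- function() {
  c("line_id", "regime", "sex", "trait", "value")
}

#' Construct a validated vial interval table
#'
#' A vial table is the long-format container for interval-censored death (or
#' eclosion) counts: one row per vial x inspection interval. Within a vial the
#' rows chain half-open intervals `(lo, hi]` starting at `lo = 0`; `deaths`
#' counts events discovered at the inspection closing the interval, and
#' `n_censored` (populated only on each vial's final row) counts individuals
#' still event-free at the last inspection. `n_start` is the number of
#' individuals at time zero and must equal `sum(deaths) + n_censored`.
#'
#' @param df data.frame with the columns of [vial_table_columns()].
#' @param check if `FALSE`, skip validation (internal use).
#' @return The data.frame with class `vial_table`.
#' @seealso [validate_vial_table()], [read_vial_table()]
#' @export
vial_table <- function(df, check = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(vial_table_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("vial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, vial_table_columns()]
  for (col in c("vial_id", "line_id", "regime", "sex", "cue", "starv")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("start_age_h", "interval_lo_h", "interval_hi_h")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("n_start", "deaths", "n_censored")) {
    df[[col]] <- as.integer(df[[col]])
  }
  class(df) <- c("vial_table", "data.frame")
  if (check) {
    report <- validate_vial_table(df)
    if (nrow(report) > 0L) {
      stop("invalid vial table:\n", format_validation_report(report))
    }
  }
  df
}

#' Validate a vial interval table
#'
#' Checks every structural invariant of the long format and returns a report
#' rather than failing: unknown factor labels, non-chaining or non-increasing
#' interval boundaries, negative counts, `n_censored` placed anywhere but a
#' vial's final row, count conservation (`sum(deaths) + n_censored == n_start`),
#' and duplicated vial ids across non-contiguous row blocks.
#'
#' @param df a `vial_table` or plain data.frame in the same layout.
#' @return data.frame with columns `vial_id`, `rule`, `message`; zero rows iff
#'   the dataset is valid.
#' @export
validate_vial_table <- function(df) {
  df <- as.data.frame(df)
  report <- list()
  flag <- function(vial_id, rule, message) {
    report[[length(report) + 1L]] <<- data.frame(
      vial_id = as.character(vial_id), rule = rule, message = message,
      stringsAsFactors = FALSE
    )
  }

  lv <- factor_levels()
  for (col in names(lv)) {
    bad <- !(df[[col]] %in% lv[[col]])
    for (i in which(bad)) {
      flag(df$vial_id[i], paste0("bad_", col),
           sprintf("unknown %s label '%s'", col, df[[col]][i]))
    }
  }

  # split preserving row order; duplicated ids in separate blocks are an error
  idx <- split(seq_len(nrow(df)), factor(df$vial_id, levels = unique(df$vial_id)))
  for (vid in names(idx)) {
    rows <- idx[[vid]]
    if (any(diff(rows) != 1L)) {
      flag(vid, "duplicate_vial_id",
           "vial_id appears in non-contiguous row blocks (duplicated vial?)")
      next
    }
    sub <- df[rows, , drop = FALSE]
    k <- nrow(sub)
    if (any(is.na(sub$deaths)) || any(sub$deaths < 0L, na.rm = TRUE)) {
      flag(vid, "negative_deaths", "deaths must be non-negative integers")
    }
    lo <- sub$interval_lo_h
    hi <- sub$interval_hi_h
    if (any(!is.finite(lo)) || any(!is.finite(hi))) {
      flag(vid, "bad_boundaries", "non-finite interval boundaries")
      next
    }
    if (lo[1] != 0) {
      flag(vid, "bad_boundaries", "first interval must start at 0")
    }
    if (any(hi <= lo)) {
      flag(vid, "bad_boundaries",
           "boundaries must be strictly increasing (zero-length interval)")
    }
    if (k > 1L && any(abs(lo[-1] - hi[-k]) > 1e-9)) {
      flag(vid, "bad_boundaries", "intervals do not chain: lo[i] must equal hi[i-1]")
    }
    cens <- sub$n_censored
    if (k > 1L && any(!is.na(cens[-k]))) {
      flag(vid, "misplaced_censored",
           "n_censored may be populated only on a vial's final row")
    }
    last_cens <- cens[k]
    if (is.na(last_cens) || last_cens < 0L) {
      flag(vid, "bad_censored", "final row must carry a non-negative n_censored")
      next
    }
    n_start <- unique(sub$n_start)
    if (length(n_start) != 1L || is.na(n_start)) {
      flag(vid, "bad_n_start", "n_start must be a single value per vial")
      next
    }
    if (!any(is.na(sub$deaths)) && sum(sub$deaths) + last_cens != n_start) {
      flag(vid, "count_mismatch",
           sprintf("counts do not sum to n_start (%d deaths + %d censored != %d)",
                   sum(sub$deaths), last_cens, n_start))
    }
  }

  if (length(report) == 0L) {
    return(data.frame(vial_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, report)
}

format_validation_report <- function(report) {
  paste(sprintf("  vial %s [%s]: %s", report$vial_id, report$rule, report$message),
        collapse = "\n")
}

#' @export
print.vial_table <- function(x, ...) {
  n_vials <- length(unique(x$vial_id))
  cat(sprintf("<vial_table> %d vials, %d rows, %d individuals (%d censored)\n",
              n_vials, nrow(x), sum(vial_starts(x)$n_start),
              sum(x$n_censored, na.rm = TRUE)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# one row per vial with its factors, n_start and last boundary
vial_starts <- function(df) {
  last <- !duplicated(df$vial_id, fromLast = TRUE)
  first <- !duplicated(df$vial_id)
  out <- df[first, c("vial_id", "line_id", "regime", "sex", "cue", "starv",
                     "start_age_h", "n_start"), drop = FALSE]
  out$last_boundary_h <- df$interval_hi_h[last]
  out$n_censored <- df$n_censored[last]
  rownames(out) <- NULL
  out
}

#' Convert a vial table to a list of per-vial records
#'
#' @param df a `vial_table`.
#' @return list with one element per vial: `vial_id`, `line_id`, `cell`
#'   (named list of the four factor labels), `start_age_h`, `n_start`,
#'   `boundaries` (increasing inspection times), `deaths`, `n_censored`.
#' @export
as_vial_records <- function(df) {
  idx <- split(seq_len(nrow(df)), factor(df$vial_id, levels = unique(df$vial_id)))
  lapply(idx, function(rows) {
    sub <- df[rows, , drop = FALSE]
    k <- nrow(sub)
    list(
      vial_id = sub$vial_id[1], line_id = sub$line_id[1],
      cell = list(regime = sub$regime[1], sex = sub$sex[1],
                  cue = sub$cue[1], starv = sub$starv[1]),
      start_age_h = sub$start_age_h[1], n_start = sub$n_start[1],
      boundaries = sub$interval_hi_h, deaths = sub$deaths,
      n_censored = sub$n_censored[k]
    )
  })
}

#' Assemble a vial table from per-vial records
#'
#' Inverse of [as_vial_records()].
#'
#' @param records list of per-vial records.
#' @return a `vial_table`.
#' @export
vial_records_to_table <- function(records) {
  parts <- lapply(records, function(r) {
    k <- length(r$boundaries)
    data.frame(
      vial_id = r$vial_id, line_id = r$line_id,
      regime = r$cell$regime, sex = r$cell$sex,
      cue = r$cell$cue, starv = r$cell$starv,
      start_age_h = r$start_age_h, n_start = r$n_start,
      interval_lo_h = c(0, r$boundaries[-k]),
      interval_hi_h = r$boundaries,
      deaths = r$deaths,
      n_censored = c(rep(NA_integer_, k - 1L), r$n_censored),
      stringsAsFactors = FALSE
    )
  })
  vial_table(do.call(rbind, parts))
}

#' Construct a validated fecundity table
#'
#' One row per female: her replicate line, treatment cell (sex is implicitly
#' female), age class at egg laying and the number of eggs laid in the 18-h
#' laying window.
#'
#' @param df data.frame with columns [fecundity_table_columns()].
#' @return data.frame with class `fecundity_table`.
#' @export
fecundity_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(fecundity_table_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("fecundity table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, fecundity_table_columns()]
  df$eggs <- as.integer(df$eggs)
  lv <- factor_levels()
  problems <- character()
  if (any(is.na(df$eggs) | df$eggs < 0L)) {
    problems <- c(problems, "eggs must be non-negative integers")
  }
  if (!all(df$age_class %in% age_class_levels())) {
    problems <- c(problems, "unknown age_class label")
  }
  for (col in c("regime", "cue", "starv")) {
    if (!all(df[[col]] %in% lv[[col]])) {
      problems <- c(problems, sprintf("unknown %s label", col))
    }
  }
  if (anyDuplicated(df$female_id)) {
    problems <- c(problems, "duplicated female_id")
  }
  if (length(problems) > 0L) {
    stop("invalid fecundity table: ", paste(problems, collapse = "; "))
  }
  class(df) <- c("fecundity_table", "data.frame")
  df
}

#' Construct a validated line-trait table
#'
#' One physiology measurement per replicate line x sex x trait (each value is
#' itself a group average over 15-20 flies in the assays this mirrors).
#'
#' @param df data.frame with columns [line_trait_table_columns()].
#' @return data.frame with class `line_trait_table`.
#' @export
line_trait_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(line_trait_table_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("line-trait table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, line_trait_table_columns()]
  df$value <- as.numeric(df$value)
  lv <- factor_levels()
  problems <- character()
  if (!all(df$trait %in% trait_levels())) problems <- c(problems, "unknown trait label")
  if (!all(df$sex %in% lv$sex)) problems <- c(problems, "unknown sex label")
  if (!all(df$regime %in% lv$regime)) problems <- c(problems, "unknown regime label")
  if (any(!is.finite(df$value))) problems <- c(problems, "non-finite trait value")
  key <- paste(df$line_id, df$sex, df$trait)
  if (anyDuplicated(key)) {
    problems <- c(problems, "more than one record per (line_id, sex, trait)")
  }
  if (length(problems) > 0L) {
    stop("invalid line-trait table: ", paste(problems, collapse = "; "))
  }
  class(df) <- c("line_trait_table", "data.frame")
  df
}
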