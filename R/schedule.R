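# Inspection schedules: regularly spaced daytime checks with one longer
# overnight gap per 24-h cycle, ending exactly at the assay end.

#' Specify an inspection schedule
#'
#' Vials are inspected every `day_spacing_h` hours during the active part of
#' each 24-h cycle, with a single longer overnight gap of `overnight_gap_h`
#' hours closing the cycle. `end_h` is the assay end (hours from the trait's
#' clock start: start of starvation, end of cold shock, or egg-laying
#' midpoint); the last inspection falls exactly at `end_h` and individuals
#' still event-free there are right censored.
#'
#' @param day_spacing_h spacing of daytime inspections, hours (> 0).
#' @param overnight_gap_h overnight gap, hours (>= `day_spacing_h`).
#' @param end_h assay end, hours (>= `day_spacing_h`).
#' @return object of class `schedule_spec`.
#' @export
schedule_spec <- function(day_spacing_h, overnight_gap_h, end_h) {
  if (!is.numeric(day_spacing_h) || day_spacing_h <= 0) {
    stop("day_spacing_h must be > 0")
  }
  if (overnight_gap_h < day_spacing_h) {
    stop("overnight_gap_h must be at least day_spacing_h")
  }
  if (overnight_gap_h >= 24) stop("overnight_gap_h must be shorter than a day")
  if (end_h < day_spacing_h) {
    stop("inconsistent schedule: assay end precedes the first inspection")
  }
  structure(list(day_spacing_h = day_spacing_h,
                 overnight_gap_h = overnight_gap_h,
                 end_h = end_h),
            class = "schedule_spec")
}

#' Build inspection boundaries from a schedule specification
#'
#' Returns the strictly increasing inspection times implied by the spec:
#' within each 24-h cycle, checks at `day_spacing_h, 2*day_spacing_h, ...` up
#' to `24 - overnight_gap_h`, then the overnight jump to the end of the cycle.
#' Boundaries are truncated so that the final boundary is exactly `end_h` and
#' no gap is shorter than `day_spacing_h`.
#'
#' @param spec a [schedule_spec()] (or a list with the same fields).
#' @return numeric vector of strictly increasing boundaries, ending at `end_h`.
#' @examples
#' make_schedule(schedule_spec(4, 12, 24))  # 4 8 12 24
#' @export
make_schedule <- function(spec) {
  if (!inherits(spec, "schedule_spec")) {
    spec <- schedule_spec(spec$day_spacing_h, spec$overnight_gap_h, spec$end_h)
  }
  sp <- spec$day_spacing_h
  day_window <- 24 - spec$overnight_gap_h
  within_day <- if (day_window + 1e-9 >= sp) {
    seq(sp, day_window + 1e-9, by = sp)
  } else {
    numeric(0)  # overnight gap leaves no room for daytime checks
  }
  n_days <- ceiling(spec$end_h / 24)
  grid <- sort(unique(c(
    rep(24 * (seq_len(n_days) - 1L), each = length(within_day)) + within_day,
    24 * seq_len(n_days)
  )))
  # keep last gap >= spacing: drop grid points inside (end - spacing, end)
  grid <- grid[grid <= spec$end_h - sp + 1e-9]
  boundaries <- c(grid, spec$end_h)
  boundaries <- boundaries[!duplicated(round(boundaries, 9))]
  stopifnot(all(diff(boundaries) > 0))
  boundaries
}
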