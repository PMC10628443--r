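#' Phase calendar of a drought experiment
#'
#' Builds the contiguous, non-overlapping calendar of the four experimental
#' phases (pre_drought, drought, recovery, post_recovery) from a start date
#' and the phase durations in days.
#'
#' @param start First day of the run (Date or character).
#' @param lengths Named numeric vector of phase durations in days, in
#'   chronological order; each >= 1.
#' @return A data frame of class `phase_calendar` with columns `phase`,
#'   `start` and `end` (inclusive dates).
#' @examples
#' phase_calendar("2023-01-27")
#' @export
phase_calendar <- function(start,
                           lengths = c(pre_drought = 7, drought = 12,
                                       recovery = 10, post_recovery = 10)) {
  start <- as.Date(start)
  if (any(lengths < 1) || any(lengths != round(lengths)))
    stopf("phase lengths must be whole numbers of days >= 1")
  if (is.null(names(lengths)) || !all(nzchar(names(lengths))))
    stopf("'lengths' must be named by phase")
  ends <- start + cumsum(lengths) - 1
  starts <- c(start, ends[-length(ends)] + 1)
  out <- data.frame(phase = names(lengths), start = starts, end = ends,
                    row.names = NULL)
  class(out) <- c("phase_calendar", "data.frame")
  out
}

#' Phase membership of dates
#'
#' @param calendar A [phase_calendar()].
#' @param dates Date vector.
#' @return Character vector of phase labels (`NA` outside the calendar).
#' @export
phase_of <- function(calendar, dates) {
  stopifnot(inherits(calendar, "phase_calendar"))
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(calendar))) {
    sel <- dates >= calendar$start[i] & dates <= calendar$end[i]
    out[sel] <- calendar$phase[i]
  }
  out
}

#' Dates belonging to one phase
#'
#' @param calendar A [phase_calendar()].
#' @param phase Phase label.
#' @return Date vector spanning the phase (inclusive).
#' @export
phase_dates <- function(calendar, phase) {
  i <- match(phase, calendar$phase)
  if (is.na(i)) stopf("phase '%s' is not in the calendar", phase)
  seq(calendar$start[i], calendar$end[i], by = "day")
}
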