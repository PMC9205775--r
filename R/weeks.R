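#' Calendar-week indexing
#'
#' All of the pipeline's temporal reasoning happens on a weekly grid. Weeks are
#' fixed Monday-start calendar weeks, identical for every patient, indexed by
#' the number of whole weeks elapsed since the epoch Monday 1970-01-05. Using an
#' absolute index (rather than a per-patient offset) keeps the week-of-year
#' seasonality encoding well defined and makes rows from different patients
#' directly comparable.
#'
#' @param date a `Date` vector.
#' @return `date_to_week()`: integer week index; `week_start()`: the `Date` of
#'   the Monday opening week `week`; `week_of_year()`: integer in 1..52.
#' @examples
#' date_to_week(as.Date("1970-01-05"))  # 0
#' week_start(date_to_week(Sys.Date())) # Monday of the current week
#' @export
date_to_week <- function(date) {
  stopifnot(inherits(date, "Date"))
  (as.integer(date) - 4L) %/% 7L
}

#' @rdname date_to_week
#' @param week integer week index as produced by `date_to_week()`.
#' @export
week_start <- function(week) {
  as.Date(as.integer(week) * 7L + 4L, origin = "1970-01-01")
}

#' @rdname date_to_week
#' @details `week_of_year()` is the 7-day block of the year the week's Monday
#'   falls in, capped at 52 so the cyclical sine/cosine encoding has a fixed
#'   period (the few days of a 53rd block are folded into week 52).
#' @export
week_of_year <- function(week) {
  yd <- as.POSIXlt(week_start(week))$yday # 0-based day of year
  pmin(yd %/% 7L + 1L, 52L)
}
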