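# Condition helpers: three error classes map onto the tool's exit-code
# contract (validation/argument errors exit 2, everything else 1).

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "hrsched_validation_error", ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = c("hrsched_argument_error", "hrsched_validation_error"), ...)
}

abort_insufficient <- function(msg, ...) {
  rlang::abort(msg, class = c("hrsched_insufficient_data", "hrsched_validation_error"), ...)
}

#' Weekday index with Monday = 0
#'
#' @param date a `Date` (or something coercible to one).
#' @return Integer 0--6; Monday is 0, Sunday 6. Weeks run Monday--Sunday so
#'   that predicted slots transfer directly to the following week.
#' @export
weekday_index <- function(date) {
  as.integer(format(as.Date(date), "%u")) - 1L
}

#' Monday of the week containing a date
#'
#' @param date a `Date`.
#' @return The `Date` of that week's Monday.
#' @export
week_monday <- function(date) {
  date <- as.Date(date)
  date - weekday_index(date)
}

#' Calendar date of a day series
#'
#' @param day a day series tibble (`time`, `bpm`).
#' @return The `Date` its samples fall on.
#' @export
day_date <- function(day) {
  as.Date(format(min(day$time), "%Y-%m-%d"))
}

WEEKDAY_NAMES <- c("Monday", "Tuesday", "Wednesday", "Thursday",
                   "Friday", "Saturday", "Sunday")
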