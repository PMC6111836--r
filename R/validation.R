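# Day-level train/validate procedure: when only a few consecutive days per
# subject exist (too little for the 3-week pipeline), one day trains a risk
# set and the next day scores it hour by hour.

#' Train a day-level risk set
#'
#' Marks as risky every hour whose hourly *maximum* bpm strictly exceeds
#' the day's [daily_threshold()]. Note the deliberate contrast with
#' [detect_risky_ranges()], which compares hourly *means*: with a single
#' training day there is no second-stage training threshold to prune noise,
#' and the hourly maximum is the more sensitive single-day statistic.
#'
#' @param day a non-empty day-series tibble.
#' @return An object of class `day_risk_set`: `hours` (risky hours),
#'   `observed_hours` (hours with at least one sample) and `threshold`.
#' @export
day_train <- function(day) {
  ex <- day_extrema(day)
  t <- daily_threshold(ex[["r_max"]], ex[["r_min"]])
  agg <- hourly_aggregate(day)
  structure(
    list(
      hours = as.integer(agg$hour[agg$max_bpm > t]),
      observed_hours = as.integer(agg$hour),
      threshold = t
    ),
    class = "day_risk_set"
  )
}

#' @export
print.day_risk_set <- function(x, ...) {
  cat(sprintf(
    "<day_risk_set> %d risky of %d observed hours (threshold %.2f bpm)\n",
    length(x$hours), length(x$observed_hours), x$threshold))
  invisible(x)
}

#' Score a trained risk set against the following day
#'
#' The validation day's own risk set is computed by [day_train()]; each hour
#' observed on *both* days is then compared, and an hour counts as a match
#' when its risk status (risky / not risky) agrees across the two days —
#' agreement on quiet hours counts just as agreement on risky ones, since
#' both mean the schedule would have sampled at the right rate. Hours
#' missing from either day carry no evidence and are excluded from the
#' denominator.
#'
#' @param trained a `day_risk_set` from the training day.
#' @param validation_day a non-empty day-series tibble.
#' @return An object of class `accuracy_result`: `matches`,
#'   `comparable_hours`, `accuracy_pct`.
#' @export
day_validate <- function(trained, validation_day) {
  if (!inherits(trained, "day_risk_set")) {
    abort_argument("`trained` must be a day_risk_set (see day_train())")
  }
  v <- day_train(validation_day)
  comparable <- intersect(trained$observed_hours, v$observed_hours)
  if (length(comparable) == 0) {
    rlang::abort(
      "no hour was observed on both days; accuracy is undefined",
      class = c("hrsched_undefined_accuracy", "hrsched_validation_error")
    )
  }
  matches <- sum((comparable %in% trained$hours) == (comparable %in% v$hours))
  structure(
    list(
      matches = as.integer(matches),
      comparable_hours = length(comparable),
      accuracy_pct = 100 * matches / length(comparable)
    ),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %d/%d hours agree: %.2f%%\n",
              x$matches, x$comparable_hours, x$accuracy_pct))
  invisible(x)
}

#' Summarise per-user accuracies over a cohort
#'
#' @param results a numeric vector of accuracy percentages, or a list of
#'   `accuracy_result` objects; at least 2.
#' @return Named list: `mean_pct` and `sd_pct` (sample standard deviation,
#'   the n-1 convention usual for a small cohort).
#' @export
cohort_summary <- function(results) {
  if (is.list(results) && !is.numeric(results)) {
    results <- vapply(results, function(r) {
      if (inherits(r, "accuracy_result")) r$accuracy_pct else as.double(r)
    }, double(1))
  }
  results <- as.double(results)
  if (length(results) < 2 || any(!is.finite(results))) {
    abort_argument("`results` must hold at least 2 finite accuracy values")
  }
  list(mean_pct = mean(results), sd_pct = stats::sd(results))
}
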