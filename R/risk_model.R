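#' Daily risk threshold from a day's heart-rate extrema
#'
#' The per-day bar an hourly mean must clear to count as risky:
#' `t = (2/3) * r_max + (1/3) * r_min`, a weighted average deliberately
#' pulled toward the maximum so that only genuinely elevated hours — not
#' every hour above the day's plain average — are flagged.
#'
#' @param r_max,r_min the day's maximum and minimum bpm (vectorised).
#' @return The threshold in bpm; always within `[r_min, r_max]`.
#' @export
daily_threshold <- function(r_max, r_min) {
  if (any(r_max < r_min)) {
    abort_argument("`r_max` must be >= `r_min`")
  }
  if (any(r_min <= 0)) {
    abort_argument("heart-rate extrema must be positive")
  }
  r_max * 2 / 3 + r_min / 3
}

#' Detect a day's risky hourly ranges
#'
#' Flags exactly the hours whose hourly *mean* bpm strictly exceeds the
#' day's [daily_threshold()] (computed from the raw sample extrema, not the
#' hourly summaries). Hours with no data contribute nothing.
#'
#' @param day a non-empty day-series tibble.
#' @return A tibble of risky ranges: `date`, `hour` (0--23), `mean_bpm`,
#'   where every `mean_bpm` strictly exceeds the daily threshold.
#' @export
detect_risky_ranges <- function(day) {
  ex <- day_extrema(day)
  t <- daily_threshold(ex[["r_max"]], ex[["r_min"]])
  agg <- hourly_aggregate(day)
  out <- agg[agg$mean_bpm > t, c("date", "hour", "mean_bpm")]
  tibble::as_tibble(out)
}

#' Training threshold over the 3-week sliding window
#'
#' Second-stage bar: `Tt = mean(week_maxima) * ratio`. A risky range enters
#' the next week's prediction only if its hourly mean strictly exceeds `Tt`.
#' The ratio (default 0.8) trades sensitivity against energy: lower ratios
#' monitor more hours at high frequency.
#'
#' @param week_maxima numeric, the maximum bpm observed in each training
#'   week (one value per week).
#' @param ratio dimensionless ratio threshold in (0, 1], default 0.8.
#' @return An object of class `training_threshold`: a list with `tt`,
#'   `ratio` and `week_maxima`.
#' @export
training_threshold <- function(week_maxima, ratio = 0.8) {
  week_maxima <- as.double(week_maxima)
  if (length(week_maxima) < 1 || any(!is.finite(week_maxima))) {
    abort_argument("`week_maxima` must hold at least one finite value")
  }
  if (!is.finite(ratio) || ratio <= 0 || ratio > 1) {
    abort_argument("`ratio` must lie in (0, 1]")
  }
  structure(
    list(tt = mean(week_maxima) * ratio, ratio = ratio, week_maxima = week_maxima),
    class = "training_threshold"
  )
}

#' @export
print.training_threshold <- function(x, ...) {
  cat(sprintf(
    "<training_threshold> tt = %.2f bpm (ratio %.2f x mean of week maxima %s)\n",
    x$tt, x$ratio, paste(format(x$week_maxima), collapse = ", ")))
  invisible(x)
}

tt_value <- function(tt) {
  if (inherits(tt, "training_threshold")) tt$tt else as.double(tt)
}

#' Build a weekly profile from raw day series
#'
#' A weekly profile bundles one Monday--Sunday week: its day summaries
#' (extrema and daily threshold), the week's maximum bpm, and all risky
#' ranges detected by [detect_risky_ranges()].
#'
#' @param days list of day-series tibbles, all within one Monday--Sunday
#'   week; days may be missing (gaps in wear).
#' @param start_date optional `Date` of the week's Monday; inferred from the
#'   first day when omitted.
#' @return An object of class `weekly_profile`.
#' @export
weekly_profile <- function(days, start_date = NULL) {
  if (length(days) == 0) {
    abort_argument("a weekly profile needs at least one day of data")
  }
  dates <- as.Date(vapply(days, function(d) as.character(day_date(d)), character(1)))
  if (is.null(start_date)) start_date <- week_monday(min(dates))
  start_date <- as.Date(start_date)
  if (weekday_index(start_date) != 0L) {
    abort_argument("`start_date` must be a Monday")
  }
  if (any(dates < start_date | dates > start_date + 6)) {
    abort_argument("all days must fall within the week starting on `start_date`")
  }
  ex <- t(vapply(days, day_extrema, c(r_max = 0, r_min = 0)))
  day_summary <- tibble::tibble(
    date = dates,
    weekday = weekday_index(dates),
    r_max = ex[, "r_max"],
    r_min = ex[, "r_min"],
    threshold = daily_threshold(ex[, "r_max"], ex[, "r_min"])
  ) |> dplyr::arrange(date)
  ranges <- dplyr::bind_rows(lapply(days, detect_risky_ranges)) |>
    dplyr::arrange(.data$date, .data$hour)
  new_weekly_profile(
    start_date = start_date,
    week_max_bpm = max(ex[, "r_max"]),
    risky_ranges = ranges,
    day_summary = day_summary,
    days = days
  )
}

#' Low-level weekly-profile constructor
#'
#' Builds a profile directly from already-summarised inputs (a week maximum
#' and a table of risky ranges), e.g. when only hourly summaries of a wear
#' record are available rather than the raw minute stream.
#'
#' @param start_date `Date` of the week's Monday.
#' @param week_max_bpm maximum bpm observed anywhere in the week.
#' @param risky_ranges tibble with columns `date`, `hour`, `mean_bpm`.
#' @param day_summary optional tibble of per-day `date`, `weekday`, `r_max`,
#'   `r_min`, `threshold`.
#' @param days optional list of the raw day series.
#' @return An object of class `weekly_profile`.
#' @export
new_weekly_profile <- function(start_date, week_max_bpm, risky_ranges,
                               day_summary = NULL, days = NULL) {
  start_date <- as.Date(start_date)
  if (weekday_index(start_date) != 0L) {
    abort_argument("`start_date` must be a Monday")
  }
  risky_ranges <- tibble::as_tibble(risky_ranges)
  if (nrow(risky_ranges) > 0) {
    risky_ranges$date <- as.Date(risky_ranges$date)
    if (any(risky_ranges$date < start_date | risky_ranges$date > start_date + 6)) {
      abort_argument("risky ranges must fall within the profile's week")
    }
    if (any(risky_ranges$hour < 0 | risky_ranges$hour > 23)) {
      abort_argument("risky-range hours must lie in 0..23")
    }
  }
  structure(
    list(
      start_date = start_date,
      week_max_bpm = as.double(week_max_bpm),
      risky_ranges = risky_ranges,
      day_summary = day_summary,
      days = days
    ),
    class = "weekly_profile"
  )
}

#' @export
print.weekly_profile <- function(x, ...) {
  cat(sprintf(
    "<weekly_profile> week of %s: max %.2f bpm, %d risky range(s)\n",
    format(x$start_date), x$week_max_bpm, nrow(x$risky_ranges)))
  invisible(x)
}

#' Filter risky ranges by the training threshold
#'
#' @param ranges a risky-range tibble (`date`, `hour`, `mean_bpm`).
#' @param tt a [training_threshold()] object or a bare bpm value.
#' @return The subset whose `mean_bpm` strictly exceeds the training
#'   threshold.
#' @export
select_prediction_ranges <- function(ranges, tt) {
  tt <- tt_value(tt)
  tibble::as_tibble(ranges[ranges$mean_bpm > tt, , drop = FALSE])
}

new_prediction <- function(slots, training = NULL) {
  slots <- tibble::as_tibble(slots[c("weekday", "hour")])
  slots$weekday <- as.integer(slots$weekday)
  slots$hour <- as.integer(slots$hour)
  if (nrow(slots) > 0 &&
      (any(slots$weekday < 0 | slots$weekday > 6) ||
       any(slots$hour < 0 | slots$hour > 23))) {
    abort_argument("prediction slots must satisfy weekday in 0..6, hour in 0..23")
  }
  slots <- dplyr::distinct(slots) |> dplyr::arrange(.data$weekday, .data$hour)
  structure(slots, class = c("hr_prediction", class(slots)), training = training)
}

#' @export
as.data.frame.hr_prediction <- function(x, ...) {
  data.frame(weekday = x$weekday, hour = x$hour)
}

#' Prediction from explicit weekday-hour slots
#'
#' @param weekday integer 0--6 (Monday = 0).
#' @param hour integer 0--23.
#' @return An `hr_prediction` tibble of unique, sorted slots.
#' @export
prediction <- function(weekday = integer(), hour = integer()) {
  new_prediction(tibble::tibble(weekday = weekday, hour = hour))
}

#' Predict next week's risk slots from a 3-week training window
#'
#' The core two-stage procedure: (1) each day's risky hourly ranges come
#' from the daily threshold; (2) the training threshold over the window's
#' three weekly maxima prunes them; (3) surviving ranges from all three
#' weeks are pooled by `(weekday, hour)` — the union across weeks, so a
#' routine observed in any single training week is still monitored.
#'
#' @param weeks list of exactly 3 [weekly_profile()] objects (the sliding
#'   training slot).
#' @param ratio ratio threshold for [training_threshold()], default 0.8.
#' @return An `hr_prediction` tibble with columns `weekday`, `hour`; its
#'   `training` attribute holds the `training_threshold` used.
#' @export
build_prediction <- function(weeks, ratio = 0.8) {
  if (!is.list(weeks) || length(weeks) != 3 ||
      !all(vapply(weeks, inherits, logical(1), "weekly_profile"))) {
    abort_argument("`weeks` must be a list of exactly 3 weekly_profile objects")
  }
  maxima <- vapply(weeks, function(w) w$week_max_bpm, double(1))
  tt <- training_threshold(maxima, ratio)
  surviving <- lapply(weeks, function(w) {
    kept <- select_prediction_ranges(w$risky_ranges, tt)
    if (nrow(kept) == 0) {
      return(tibble::tibble(weekday = integer(), hour = integer()))
    }
    tibble::tibble(weekday = weekday_index(kept$date), hour = as.integer(kept$hour))
  })
  new_prediction(dplyr::bind_rows(surviving), training = tt)
}

#' Re-learn the prediction after possible routine changes
#'
#' Run once per week over the latest 3-week window: ranges in the new window
#' that clear the freshly recomputed training threshold are added and
#' marked; previously predicted slots not re-confirmed by the window are
#' swept away. The result therefore always equals [build_prediction()] on
#' the current window — the mark-and-sweep phrasing just makes explicit that
#' stale slots (an abandoned exercise routine) are dropped.
#'
#' @param history list of the latest 3 [weekly_profile()] objects.
#' @param previous the previous `hr_prediction` (may be `NULL` on first run).
#' @param ratio ratio threshold, default 0.8.
#' @return The updated `hr_prediction`.
#' @export
recalculate_routines <- function(history, previous = NULL, ratio = 0.8) {
  fresh <- build_prediction(history, ratio)
  prev <- if (is.null(previous)) {
    tibble::tibble(weekday = integer(), hour = integer())
  } else {
    tibble::as_tibble(previous)[c("weekday", "hour")]
  }
  # mark: every slot confirmed by the new window (whether or not previously
  # predicted); sweep: unmarked carried-over slots are removed
  pool <- dplyr::bind_rows(
    dplyr::mutate(prev, marked = FALSE),
    dplyr::mutate(tibble::as_tibble(fresh)[c("weekday", "hour")], marked = TRUE)
  ) |>
    dplyr::group_by(.data$weekday, .data$hour) |>
    dplyr::summarise(marked = any(.data$marked), .groups = "drop") |>
    dplyr::filter(.data$marked)
  new_prediction(pool[c("weekday", "hour")], training = attr(fresh, "training"))
}

#' Format a weekly profile as the per-week report table
#'
#' One row per observed day: weekday name, the day's maximum bpm and daily
#' threshold, its risky ranges as `"h-h+1:mean"` strings, and (when a
#' training threshold is supplied) the subset of ranges above it. bpm values
#' are rounded to 2 decimals for display only; all comparisons inside the
#' pipeline use full precision.
#'
#' @param week a `weekly_profile`.
#' @param tt optional [training_threshold()] or bpm value.
#' @return A tibble: `day`, `max_pulsation`, `threshold`, `ranges`, `date`,
#'   `ranges_above_tt`.
#' @export
format_week_table <- function(week, tt = NULL) {
  fmt_range <- function(h, m) sprintf("%d-%d:%.2f", h, (h + 1L) %% 24L, m)
  fmt_slot <- function(h) sprintf("%d-%d", h, (h + 1L) %% 24L)
  summ <- week$day_summary
  if (is.null(summ)) {
    dates <- sort(unique(week$risky_ranges$date))
    summ <- tibble::tibble(
      date = dates, weekday = weekday_index(dates),
      r_max = NA_real_, threshold = NA_real_
    )
  }
  ranges <- week$risky_ranges
  per_day <- function(d) {
    r <- ranges[ranges$date == d, ]
    list(
      ranges = if (nrow(r) == 0) "-" else
        paste(fmt_range(r$hour, r$mean_bpm), collapse = ";"),
      above = if (is.null(tt)) NA_character_ else {
        keep <- r[r$mean_bpm > tt_value(tt), ]
        if (nrow(keep) == 0) "-" else paste(fmt_slot(keep$hour), collapse = ";")
      }
    )
  }
  cells <- lapply(summ$date, per_day)
  tibble::tibble(
    day = WEEKDAY_NAMES[summ$weekday + 1L],
    max_pulsation = round(summ$r_max, 2),
    threshold = round(summ$threshold, 2),
    ranges = vapply(cells, `[[`, character(1), "ranges"),
    date = summ$date,
    ranges_above_tt = vapply(cells, `[[`, character(1), "above")
  )
}

#' Write a weekly report table as TSV
#'
#' @inheritParams format_week_table
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_week_tsv <- function(week, path, tt = NULL) {
  readr::write_tsv(format_week_table(week, tt), path, progress = FALSE)
  invisible(path)
}

#' Serialise / deserialise a prediction as JSON
#'
#' @param pred an `hr_prediction`.
#' @param path file path.
#' @return `write_prediction_json()` returns `path` invisibly;
#'   `read_prediction_json()` returns the `hr_prediction`.
#' @export
write_prediction_json <- function(pred, path) {
  tt <- attr(pred, "training", exact = TRUE)
  payload <- list(slots = tibble::as_tibble(pred)[c("weekday", "hour")])
  if (!is.null(tt)) {
    payload$training <- list(tt = tt$tt, ratio = tt$ratio, week_maxima = tt$week_maxima)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prediction_json
#' @export
read_prediction_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  slots <- tibble::as_tibble(payload$slots)
  if (nrow(slots) == 0) slots <- tibble::tibble(weekday = integer(), hour = integer())
  tt <- NULL
  if (!is.null(payload$training)) {
    tt <- training_threshold(payload$training$week_maxima, payload$training$ratio)
  }
  new_prediction(slots, training = tt)
}
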