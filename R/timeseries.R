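#' Construct a validated heart-rate sample stream
#'
#' The universal input of the package: one row per measurement, minute
#' resolution. Rows are sorted by time; physiologically impossible readings
#' and duplicate timestamps are rejected (the source device emits at most one
#' reading per minute, so a duplicate indicates corrupt data, not something
#' to average away).
#'
#' @param time `POSIXct` measurement instants.
#' @param bpm numeric heart rates, beats per minute; must lie in (0, 300).
#' @return A tibble with columns `time` (POSIXct) and `bpm` (double),
#'   sorted by `time`.
#' @export
hr_samples <- function(time, bpm) {
  if (length(time) != length(bpm)) {
    abort_argument("`time` and `bpm` must have the same length.")
  }
  time <- as.POSIXct(time, tz = "UTC")
  bpm <- as.double(bpm)
  bad <- which(!is.finite(bpm) | bpm <= 0 | bpm >= 300)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "bpm out of range (0, 300) at row %d: %s", bad[1], format(bpm[bad[1]])))
  }
  ord <- order(time)
  time <- time[ord]
  bpm <- bpm[ord]
  dup <- which(duplicated(time))
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "duplicate timestamp: %s", format(time[dup[1]], "%Y-%m-%d %H:%M:%S")))
  }
  tibble::tibble(time = time, bpm = bpm)
}

#' Read heart-rate samples from CSV, grouped by calendar day
#'
#' Reads the package's fixed CSV dialect — header `timestamp,bpm`, ISO-8601
#' timestamps, UTF-8 — validates every row, and splits the stream at
#' midnight into per-day series. Out-of-order rows are sorted; a sample at
#' exactly 00:00 belongs to the day that is starting.
#'
#' @param path path to a CSV file.
#' @return A list of day-series tibbles (columns `time`, `bpm`), one per
#'   calendar date present, in date order.
#' @export
read_samples <- function(path) {
  split_days(read_hr_csv(path))
}

#' Read a heart-rate CSV into a single sample tibble
#'
#' @inheritParams read_samples
#' @return A validated sample tibble (see [hr_samples()]).
#' @export
read_hr_csv <- function(path) {
  if (!file.exists(path)) {
    abort_argument(sprintf("file not found: %s", path))
  }
  # parse problems are re-raised below as hrsched errors naming the line
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      bpm = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort_validation(sprintf(
      "malformed row at line %d of %s (expected `timestamp,bpm`)",
      probs$row[1], path))
  }
  if (!all(c("timestamp", "bpm") %in% names(raw))) {
    abort_validation(sprintf("missing `timestamp,bpm` header in %s", path))
  }
  bad <- which(is.na(raw$timestamp) | is.na(raw$bpm))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "malformed row at line %d of %s (unparseable timestamp or bpm)",
      bad[1] + 1L, path))
  }
  hr_samples(raw$timestamp, raw$bpm)
}

#' Write samples in the package CSV dialect
#'
#' @param x a sample or day-series tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(x, path) {
  out <- tibble::tibble(
    timestamp = format(x$time, "%Y-%m-%dT%H:%M:%S"),
    bpm = x$bpm
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a sample stream into per-day series
#'
#' @param samples a sample tibble from [hr_samples()] or [read_hr_csv()].
#' @return List of day-series tibbles in date order.
#' @export
split_days <- function(samples) {
  if (nrow(samples) == 0) return(list())
  date <- as.Date(format(samples$time, "%Y-%m-%d"))
  out <- split(samples[c("time", "bpm")], date)
  out <- out[order(as.Date(names(out)))]
  unname(lapply(out, tibble::as_tibble))
}

#' Fill measurement gaps by linear interpolation
#'
#' Wearable streams have gaps (dirty sensor glass, loose fit). This puts a
#' day on the regular 1-minute grid between its first and last sample,
#' keeping observed samples exactly and filling gaps linearly between the
#' flanking observations. No extrapolation happens beyond the endpoints, and
#' gaps are never filled across midnight: days are analysed independently.
#'
#' @param day a day-series tibble with at least 2 samples.
#' @param step grid step in seconds (default 60, the device's nominal rate).
#' @return A day-series tibble on the regular grid with an added logical
#'   column `interpolated`, and attribute `missing_fraction` = filled points
#'   / grid points (also available via [missing_fraction()]).
#' @export
interpolate_missing <- function(day, step = 60) {
  if (nrow(day) < 2) {
    abort_insufficient("need at least 2 samples to interpolate a day")
  }
  t0 <- as.numeric(day$time)
  grid <- seq(min(t0), max(t0), by = step)
  fit <- stats::approx(t0, day$bpm, xout = grid, method = "linear")
  observed <- grid %in% t0
  out <- tibble::tibble(
    time = as.POSIXct(grid, tz = "UTC"),
    bpm = fit$y,
    interpolated = !observed
  )
  # observed samples are carried over bit-exactly, not re-interpolated
  out$bpm[observed] <- day$bpm[match(grid[observed], t0)]
  attr(out, "missing_fraction") <- sum(!observed) / length(grid)
  out
}

#' Fraction of grid points that had to be interpolated
#'
#' @param day the result of [interpolate_missing()].
#' @return Numeric in \[0, 1\]: filled points / total grid points.
#' @export
missing_fraction <- function(day) {
  mf <- attr(day, "missing_fraction", exact = TRUE)
  if (is.null(mf)) {
    abort_argument("`day` has no missing_fraction; run interpolate_missing() first")
  }
  mf
}

#' Aggregate samples into hourly mean/max buckets
#'
#' Buckets are half-open hours \[h, h+1) in local clock time — the "0-1" ...
#' "23-0" ranges all thresholds compare against. Hours without any sample
#' produce no row (never a zero): absence of data is not a reading.
#'
#' @param day a day-series tibble (a multi-day stream also works; rows are
#'   grouped by date and hour).
#' @return A tibble with columns `date`, `hour` (0--23), `mean_bpm`,
#'   `max_bpm`, `n`, one row per (date, hour) having `n >= 1`.
#' @export
hourly_aggregate <- function(day) {
  if (nrow(day) == 0) {
    return(tibble::tibble(
      date = as.Date(character()), hour = integer(),
      mean_bpm = double(), max_bpm = double(), n = integer()
    ))
  }
  tibble::tibble(
    date = as.Date(format(day$time, "%Y-%m-%d")),
    hour = as.integer(format(day$time, "%H")),
    bpm = day$bpm
  ) |>
    dplyr::group_by(date, .data$hour) |>
    dplyr::summarise(
      mean_bpm = mean(.data$bpm),
      max_bpm = max(.data$bpm),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(date, .data$hour)
}

#' Daily heart-rate extrema
#'
#' @param day a non-empty day-series tibble.
#' @return Named numeric vector `c(r_max = , r_min = )`, both attained by
#'   some sample of the day.
#' @export
day_extrema <- function(day) {
  if (is.null(day) || nrow(day) == 0) {
    abort_insufficient("cannot take extrema of an empty day")
  }
  c(r_max = max(day$bpm), r_min = min(day$bpm))
}

#' Write hourly aggregates as TSV
#'
#' @param agg output of [hourly_aggregate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hourly_tsv <- function(agg, path) {
  readr::write_tsv(agg, path, progress = FALSE)
  invisible(path)
}
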