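# Synthetic routine generator: piecewise-mean daily traces (sleep, waking
# baseline, scheduled exercise bouts) with Gaussian minute noise and uniform
# random sample dropout. Everything downstream is testable against it
# because the true risk slots are the profile's exercise slots.

#' Describe a wearer's weekly routine
#'
#' @param sleep_window length-2 hours `c(start, end)` of the nightly sleep
#'   block (default 00:00--08:00), during which the mean sits at
#'   `sleep_bpm`.
#' @param sleep_bpm resting mean during sleep, default 65 bpm.
#' @param day_bpm_range plausible waking band `c(low, high)`, default
#'   `c(60, 100)`; the waking mean is its midpoint, and each day briefly
#'   touches the high end around midday (ordinary exertion), so a quiet
#'   day's maximum sits well above its hourly means as it does in real
#'   traces.
#' @param exercise_slots tibble (or data.frame) with columns `weekday`
#'   (0--6, Monday = 0), `start_hour`, `end_hour` (half-open hours) and
#'   `peak_bpm`; `NULL` for a routine with no exercise.
#' @param noise_sd per-minute Gaussian noise, bpm, default 3 (traces are
#'   truncated to the physiological band 40--200 bpm).
#' @param missing_rate fraction of minute samples the band fails to record,
#'   in \[0, 0.2); default 0.05, within the few-percent dropout seen on
#'   well-worn devices.
#' @param seed integer; the generator is fully deterministic given the
#'   profile's seed.
#' @return An object of class `routine_profile`.
#' @export
routine_profile <- function(sleep_window = c(0, 8),
                            sleep_bpm = 65,
                            day_bpm_range = c(60, 100),
                            exercise_slots = NULL,
                            noise_sd = 3,
                            missing_rate = 0.05,
                            seed = 1L) {
  if (length(sleep_window) != 2 || sleep_window[1] < 0 || sleep_window[2] > 24 ||
      sleep_window[1] >= sleep_window[2]) {
    abort_validation("`sleep_window` must be an increasing pair within [0, 24]")
  }
  if (length(day_bpm_range) != 2 || day_bpm_range[1] >= day_bpm_range[2]) {
    abort_validation("`day_bpm_range` must be an increasing pair")
  }
  if (is.null(exercise_slots)) {
    exercise_slots <- tibble::tibble(
      weekday = integer(), start_hour = integer(),
      end_hour = integer(), peak_bpm = double()
    )
  }
  exercise_slots <- tibble::as_tibble(exercise_slots)
  needed <- c("weekday", "start_hour", "end_hour", "peak_bpm")
  if (!all(needed %in% names(exercise_slots))) {
    abort_validation("`exercise_slots` needs columns weekday, start_hour, end_hour, peak_bpm")
  }
  if (nrow(exercise_slots) > 0) {
    with(exercise_slots, {
      if (any(weekday < 0 | weekday > 6) ||
          any(start_hour < 0 | end_hour > 24 | start_hour >= end_hour)) {
        abort_validation("exercise slots must satisfy weekday in 0..6 and 0 <= start < end <= 24")
      }
      if (any(peak_bpm <= day_bpm_range[2])) {
        abort_validation("exercise `peak_bpm` must exceed the waking band's high end")
      }
    })
  }
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 0.2) {
    abort_validation("`missing_rate` must lie in [0, 0.2)")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort_validation("`noise_sd` must be non-negative")
  }
  structure(
    list(
      sleep_window = as.double(sleep_window),
      sleep_bpm = as.double(sleep_bpm),
      day_bpm_range = as.double(day_bpm_range),
      exercise_slots = exercise_slots,
      noise_sd = as.double(noise_sd),
      missing_rate = as.double(missing_rate),
      seed = as.integer(seed)
    ),
    class = "routine_profile"
  )
}

# Minute-resolution mean curve for one weekday: sleep level, waking level
# with a brief midday excursion to the top of the waking band (ordinary
# exertion like a brisk walk, which lifts the day's maximum without lifting
# any hourly mean), and for each exercise bout a 10-min linear ramp up to
# the peak followed by a 30-min linear decay back to baseline afterwards.
day_mean_curve <- function(profile, wday,
                           ramp_min = 10L, decay_min = 30L) {
  minute <- 0:1439
  hour <- minute / 60
  waking <- !(hour >= profile$sleep_window[1] & hour < profile$sleep_window[2])
  mu <- ifelse(waking, mean(profile$day_bpm_range), profile$sleep_bpm)
  midday <- 720:729
  lift <- midday[waking[midday + 1L]]
  mu[lift + 1L] <- profile$day_bpm_range[2]
  slots <- profile$exercise_slots
  slots <- slots[slots$weekday == wday, , drop = FALSE]
  if (nrow(slots) > 0) {
    for (i in seq_len(nrow(slots))) {
      s <- as.integer(slots$start_hour[i] * 60)
      e <- as.integer(slots$end_hour[i] * 60)
      peak <- slots$peak_bpm[i]
      base <- mu[s + 1L]
      ramp_idx <- s:min(s + ramp_min - 1L, e - 1L)
      mu[ramp_idx + 1L] <- base + (peak - base) * (seq_along(ramp_idx) / length(ramp_idx))
      if (e - 1L > max(ramp_idx)) {
        mu[(max(ramp_idx) + 1L):(e - 1L) + 1L] <- peak
      }
      if (e <= 1439L) {
        decay_idx <- e:min(e + decay_min - 1L, 1439L)
        target <- mu[decay_idx + 1L]
        frac <- seq_along(decay_idx) / (decay_min + 1L)
        mu[decay_idx + 1L] <- peak + (target - peak) * frac
      }
    }
  }
  mu
}

day_seed <- function(profile, date) {
  (abs(profile$seed) * 1000L + as.integer(as.Date(date)) %% 100000L) %%
    .Machine$integer.max
}

#' Generate one synthetic day of heart-rate samples
#'
#' Produces a 1-minute trace for `date` following the profile's routine for
#' that weekday, adds Gaussian noise truncated to \[40, 200\] bpm, then
#' drops each minute independently with probability `missing_rate`. The
#' output is a deterministic function of (profile seed, date).
#'
#' @param profile a [routine_profile()].
#' @param date calendar `Date` of the day to generate.
#' @return A day-series tibble (`time`, `bpm`).
#' @export
generate_day <- function(profile, date) {
  if (!inherits(profile, "routine_profile")) {
    abort_argument("`profile` must be a routine_profile")
  }
  date <- as.Date(date)
  mu <- day_mean_curve(profile, weekday_index(date))
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(day_seed(profile, date))
  bpm <- mu + if (profile$noise_sd > 0) rnorm(1440, 0, profile$noise_sd) else 0
  bpm <- pmin(pmax(bpm, 40), 200)
  keep <- runif(1440) >= profile$missing_rate
  time <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 60 * (0:1439)
  tibble::tibble(time = time[keep], bpm = bpm[keep])
}

#' Generate consecutive synthetic weeks, optionally with a routine change
#'
#' @param profile the initial [routine_profile()].
#' @param n_weeks number of Monday--Sunday weeks to generate, >= 1.
#' @param start_date `Date` of the first week's Monday.
#' @param change_at optional 1-based week index from which `new_profile`
#'   replaces `profile` (models a wearer changing routine mid-study).
#' @param new_profile the replacement [routine_profile()] (required when
#'   `change_at` is given).
#' @return A list of `n_weeks` [weekly_profile()] objects.
#' @export
generate_weeks <- function(profile, n_weeks,
                           start_date = as.Date("2018-04-16"),
                           change_at = NULL, new_profile = NULL) {
  if (n_weeks < 1) abort_argument("`n_weeks` must be >= 1")
  start_date <- as.Date(start_date)
  if (weekday_index(start_date) != 0L) {
    abort_argument("`start_date` must be a Monday")
  }
  if (!is.null(change_at) && is.null(new_profile)) {
    abort_argument("`new_profile` is required when `change_at` is set")
  }
  lapply(seq_len(n_weeks), function(w) {
    p <- if (!is.null(change_at) && w >= change_at) new_profile else profile
    monday <- start_date + 7 * (w - 1)
    days <- lapply(0:6, function(d) generate_day(p, monday + d))
    weekly_profile(days, start_date = monday)
  })
}
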