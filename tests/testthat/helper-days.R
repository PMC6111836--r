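# Crafted day builders used across the suite.

# One sample per minute for every hour named in `bpm_by_hour`
# (names = hour 0..23, values = constant bpm held through that hour).
make_day <- function(date, bpm_by_hour, per_hour = 60) {
  date <- as.Date(date)
  hours <- as.integer(names(bpm_by_hour))
  time <- bpm <- NULL
  for (i in seq_along(hours)) {
    mins <- seq(0, 59, length.out = per_hour)
    time <- c(time, as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
                hours[i] * 3600 + round(mins) * 60)
    bpm <- c(bpm, rep(bpm_by_hour[[i]], per_hour))
  }
  hrsched::hr_samples(as.POSIXct(time, tz = "UTC", origin = "1970-01-01"), bpm)
}

# Flat day at `base` bpm over `observed_hours`, with one-sample spikes at the
# given hours: the hourly max jumps to `spike_bpm` while the mean barely moves.
make_spike_day <- function(date, spike_hours, base = 70, spike_bpm = 150,
                           observed_hours = 0:23, per_hour = 12) {
  date <- as.Date(date)
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  time <- bpm <- NULL
  for (h in observed_hours) {
    mins <- round(seq(0, 55, length.out = per_hour))
    v <- rep(base, per_hour)
    if (h %in% spike_hours) v[1] <- spike_bpm
    time <- c(time, midnight + h * 3600 + mins * 60)
    bpm <- c(bpm, v)
  }
  hrsched::hr_samples(as.POSIXct(time, tz = "UTC", origin = "1970-01-01"), bpm)
}

# The 12-slot printed weekly risk schedule used by the energy worked example
# (Thu 21-22/22-23, Fri 19-20/21-22/22-23/23-0, Sat 0-1/1-2/2-3,
#  Sun 16-17/17-18/20-21).
schedule_12 <- function() {
  hrsched::prediction(
    weekday = c(3, 3, 4, 4, 4, 4, 5, 5, 5, 6, 6, 6),
    hour    = c(21, 22, 19, 21, 22, 23, 0, 1, 2, 16, 17, 20)
  )
}

# The 4-slot schedule of the first validation week
# (Thu 21-22, Sat 0-1/2-3, Sun 17-18).
schedule_4 <- function() {
  hrsched::prediction(weekday = c(3, 5, 5, 6), hour = c(21, 0, 2, 17))
}

# The 20 published per-user day-level accuracies of the public-repository
# cohort.
cohort_accuracies <- function() {
  c(62.50, 70.83, 35.29, 62.50, 70.00, 95.00, 70.00, 52.63, 73.68, 42.10,
    50.00, 84.21, 70.83, 61.53, 58.33, 42.10, 61.90, 95.65, 68.42, 33.33)
}

# Random routine profile for property tests: 0-3 exercise bouts at daytime
# hours with peaks high enough to clear any training threshold they create.
random_profile <- function(seed) {
  set.seed(seed)
  n_slots <- sample(0:3, 1)
  slots <- NULL
  if (n_slots > 0) {
    slots <- tibble::tibble(
      weekday = sample(0:6, n_slots),
      start_hour = sample(9:21, n_slots, replace = TRUE),
      peak_bpm = runif(n_slots, 105, 134)
    )
    slots$end_hour <- slots$start_hour + sample(1:2, n_slots, replace = TRUE)
  }
  hrsched::routine_profile(
    exercise_slots = slots,
    noise_sd = runif(1, 1, 4),
    missing_rate = runif(1, 0, 0.1),
    seed = seed
  )
}

# Independent re-derivation of build_prediction from raw day series: every
# hourly mean, extremum, threshold and comparison recomputed with base R.
brute_force_prediction <- function(weeks, ratio = 0.8) {
  week_max <- numeric(length(weeks))
  all_slots <- list()
  for (w in seq_along(weeks)) {
    days <- weeks[[w]]$days
    week_max[w] <- max(vapply(days, function(d) max(d$bpm), 0))
  }
  tt <- mean(week_max) * ratio
  k <- 1
  for (w in seq_along(weeks)) {
    for (d in weeks[[w]]$days) {
      t_day <- (2 / 3) * max(d$bpm) + (1 / 3) * min(d$bpm)
      hrs <- as.integer(format(d$time, "%H"))
      for (h in unique(hrs)) {
        m <- mean(d$bpm[hrs == h])
        if (m > t_day && m > tt) {
          wd <- as.integer(format(as.Date(format(d$time[1], "%Y-%m-%d")), "%u")) - 1L
          all_slots[[k]] <- c(wd, h)
          k <- k + 1
        }
      }
    }
  }
  if (length(all_slots) == 0) {
    return(data.frame(weekday = integer(), hour = integer()))
  }
  out <- unique(do.call(rbind, all_slots))
  out <- data.frame(weekday = out[, 1], hour = out[, 2])
  out[order(out$weekday, out$hour), , drop = FALSE]
}
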