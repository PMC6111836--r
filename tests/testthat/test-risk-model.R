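test_that("daily threshold is the 2:1 weighted average of the extrema", {
  expect_equal(daily_threshold(120, 60), 100)
  expect_equal(daily_threshold(93, 49), (2 / 3) * 93 + 49 / 3)
  expect_equal(round(daily_threshold(93, 49), 2), 78.33)
  expect_equal(daily_threshold(70, 70), 70)  # convex combination of equals
  expect_error(daily_threshold(60, 120), class = "hrsched_argument_error")
  expect_error(daily_threshold(60, -1), class = "hrsched_argument_error")

  # always inside [r_min, r_max]
  set.seed(42)
  for (i in 1:50) {
    lo <- runif(1, 40, 100)
    hi <- lo + runif(1, 0, 80)
    t <- daily_threshold(hi, lo)
    expect_true(t >= lo && t <= hi)
  }
})

test_that("risky ranges are exactly the hours whose mean clears the daily bar", {
  # constant day: threshold equals the constant, strict > flags nothing
  flat <- make_day("2018-05-07", stats::setNames(rep(75, 24), 0:23), per_hour = 10)
  expect_equal(nrow(detect_risky_ranges(flat)), 0)

  # crafted day: extrema 134/52 give threshold 106.67; hour 21 mean 118.36
  day <- make_day("2018-04-19",
                  c(`3` = 52, `9` = 95, `15` = 100), per_hour = 5)
  h21 <- hr_samples(
    as.POSIXct("2018-04-19 21:00:00", tz = "UTC") + 60 * (0:4),
    c(134, 118, 118, 118, 103.8)  # mean 118.36, attains the day max
  )
  day <- hr_samples(c(day$time, h21$time), c(day$bpm, h21$bpm))
  t <- daily_threshold(134, 52)
  expect_equal(round(t, 2), 106.67)
  risky <- detect_risky_ranges(day)
  expect_equal(risky$hour, 21L)
  expect_equal(risky$mean_bpm, 118.36)

  # brute-force oracle: enumerate every hourly mean independently
  set.seed(7)
  rand <- make_day("2018-05-09", stats::setNames(runif(24, 60, 130), 0:23),
                   per_hour = 6)
  ex <- day_extrema(rand)
  t <- (2 / 3) * ex[["r_max"]] + (1 / 3) * ex[["r_min"]]
  hrs <- as.integer(format(rand$time, "%H"))
  uh <- sort(unique(hrs))
  expected <- uh[vapply(uh, function(h) mean(rand$bpm[hrs == h]) > t, logical(1))]
  expect_equal(detect_risky_ranges(rand)$hour, expected)
})

test_that("training threshold is ratio times the mean of weekly maxima", {
  tt1 <- training_threshold(c(134, 123, 134), 0.8)
  expect_equal(round(tt1$tt, 2), 104.27)
  tt2 <- training_threshold(c(134, 123, 112), 0.8)
  expect_equal(tt2$tt, 98.40)
  expect_equal(training_threshold(100, 1.0)$tt, 100)
  expect_true(tt1$tt <= max(tt1$week_maxima))
  expect_error(training_threshold(numeric(0)), class = "hrsched_argument_error")
  expect_error(training_threshold(120, ratio = 0), class = "hrsched_argument_error")
  expect_error(training_threshold(120, ratio = 1.2), class = "hrsched_argument_error")
})

test_that("prediction-range selection is strictly greater-than", {
  saturday <- tibble::tibble(
    date = as.Date("2018-04-21"), hour = c(0L, 1L, 2L),
    mean_bpm = c(106.00, 99.64, 110.60)
  )
  tt <- training_threshold(c(134, 123, 134), 0.8)
  expect_equal(select_prediction_ranges(saturday, tt)$hour, c(0L, 2L))

  # a mean just below the bar is excluded: 104.00 < 104.27
  thursday <- tibble::tibble(
    date = as.Date("2018-05-03"), hour = c(21L, 22L),
    mean_bpm = c(107.36, 104.00)
  )
  expect_equal(select_prediction_ranges(thursday, tt)$hour, 21L)
  # ... and an exact tie is excluded too (strict comparison)
  tie <- tibble::tibble(date = as.Date("2018-05-03"), hour = 5L, mean_bpm = tt$tt)
  expect_equal(nrow(select_prediction_ranges(tie, tt)), 0)
  expect_equal(nrow(select_prediction_ranges(saturday[0, ], tt)), 0)
})

test_that("3-week union prediction reproduces the worked example", {
  weeks <- example_weeks(1:3)
  pred <- build_prediction(weeks)
  expect_equal(
    as.data.frame(pred),
    data.frame(weekday = c(3L, 5L, 5L, 6L), hour = c(21L, 0L, 2L, 17L))
  )
  tt <- attr(pred, "training")
  expect_equal(round(tt$tt, 2), 104.27)
  expect_equal(tt$week_maxima, c(134, 123, 134))

  # invariant to the order the weeks are given in
  expect_equal(as.data.frame(build_prediction(weeks[c(3, 1, 2)])),
               as.data.frame(pred))

  # raising the ratio never adds slots
  for (r in c(0.85, 0.9, 0.95, 1)) {
    smaller <- as.data.frame(build_prediction(weeks, ratio = r))
    expect_true(nrow(dplyr::anti_join(
      smaller, as.data.frame(build_prediction(weeks, ratio = r - 0.05)),
      by = c("weekday", "hour"))) == 0)
  }

  expect_error(build_prediction(weeks[1:2]), class = "hrsched_argument_error")
})

test_that("second training window predicts the later schedule up to the strict-rule slot", {
  weeks <- example_weeks(c(1, 2, 4))
  pred <- build_prediction(weeks)
  expect_equal(attr(pred, "training")$tt, 98.40)
  # Friday 23-0 (mean 98.00) sits below the 98.40 bar, so the published
  # 12-slot schedule loses exactly that slot under the strict comparison
  expected <- dplyr::anti_join(
    as.data.frame(schedule_12()),
    data.frame(weekday = 4L, hour = 23L),
    by = c("weekday", "hour")
  )
  expect_equal(as.data.frame(pred), expected)
})

test_that("weekly profiles from raw days validate dates and summarise extrema", {
  prof <- routine_profile(noise_sd = 0, missing_rate = 0,
                          exercise_slots = tibble::tibble(
                            weekday = 3L, start_hour = 21L,
                            end_hour = 22L, peak_bpm = 120))
  days <- lapply(as.Date("2018-04-16") + 0:6, generate_day, profile = prof)
  wk <- weekly_profile(days)
  expect_s3_class(wk, "weekly_profile")
  expect_equal(wk$start_date, as.Date("2018-04-16"))
  expect_equal(wk$week_max_bpm, 120)
  expect_equal(nrow(wk$day_summary), 7)
  expect_error(weekly_profile(days, start_date = as.Date("2018-04-17")),
               class = "hrsched_argument_error")
  expect_error(weekly_profile(days, start_date = as.Date("2018-04-23")),
               class = "hrsched_argument_error")
})

test_that("routine recalculation equals re-prediction and adapts to change", {
  old_prof <- routine_profile(
    noise_sd = 0, missing_rate = 0,
    exercise_slots = tibble::tibble(weekday = 3L, start_hour = 21L,
                                    end_hour = 22L, peak_bpm = 120))
  new_prof <- routine_profile(
    noise_sd = 0, missing_rate = 0,
    exercise_slots = tibble::tibble(weekday = 1L, start_hour = 18L,
                                    end_hour = 19L, peak_bpm = 120))
  weeks <- generate_weeks(old_prof, 6, change_at = 4, new_profile = new_prof)

  before <- build_prediction(weeks[1:3])
  expect_equal(as.data.frame(before), data.frame(weekday = 3L, hour = 21L))

  # unchanged history is a fixed point
  again <- recalculate_routines(weeks[1:3], previous = before)
  expect_equal(as.data.frame(again), as.data.frame(before))

  # after 3 post-switch weeks the Thursday slot is swept, Tuesday marked
  after <- recalculate_routines(weeks[4:6], previous = before)
  expect_equal(as.data.frame(after), data.frame(weekday = 1L, hour = 18L))
  expect_equal(as.data.frame(after),
               as.data.frame(build_prediction(weeks[4:6])))
})

test_that("predictions round-trip through JSON and week tables render", {
  pred <- build_prediction(example_weeks(1:3))
  path <- withr::local_tempfile(fileext = ".json")
  write_prediction_json(pred, path)
  back <- read_prediction_json(path)
  expect_equal(as.data.frame(back), as.data.frame(pred))
  expect_equal(attr(back, "training")$tt, attr(pred, "training")$tt)

  empty <- prediction()
  write_prediction_json(empty, path)
  expect_equal(nrow(read_prediction_json(path)), 0)

  tab <- format_week_table(example_weeks(1)[[1]], tt = 104.27)
  expect_equal(tab$day[1], "Monday")
  expect_equal(tab$max_pulsation, c(121, 97, 108, 134, 108, 119, 117))
  expect_equal(tab$ranges_above_tt[tab$day == "Thursday"], "21-22")
  expect_equal(tab$ranges[tab$day == "Monday"], "-")
  expect_equal(tab$ranges_above_tt[tab$day == "Saturday"], "0-1;2-3")
})
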