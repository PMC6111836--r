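#' Bundled example training weeks
#'
#' Hourly risk summaries from a multi-week wear record of a single user,
#' shipped as plain TSV under `inst/extdata`: per-day maximum pulsations and
#' the risky hourly ranges (hour, mean bpm) each day's threshold flagged.
#' Weeks 1--3 form a training window whose exercise routine peaks on
#' Thursday evenings; week 4 is a quieter later week useful as an alternate
#' third training week.
#'
#' @param weeks which of the bundled weeks (1--4) to load.
#' @return A list of [weekly_profile()] objects, one per requested week.
#' @export
example_weeks <- function(weeks = 1:3) {
  maxima <- readr::read_tsv(
    system.file("extdata", "example_day_maxima.tsv", package = "hrsched"),
    col_types = "iDd", progress = FALSE
  )
  ranges <- readr::read_tsv(
    system.file("extdata", "example_risky_ranges.tsv", package = "hrsched"),
    col_types = "iDid", progress = FALSE
  )
  if (!all(weeks %in% unique(maxima$week))) {
    abort_argument("requested week not present in the bundled example record")
  }
  lapply(weeks, function(w) {
    m <- maxima[maxima$week == w, ]
    r <- ranges[ranges$week == w, c("date", "hour", "mean_bpm")]
    new_weekly_profile(
      start_date = week_monday(min(m$date)),
      week_max_bpm = max(m$max_bpm),
      risky_ranges = r,
      day_summary = tibble::tibble(
        date = m$date,
        weekday = weekday_index(m$date),
        r_max = m$max_bpm,
        r_min = NA_real_,
        threshold = NA_real_
      )
    )
  })
}
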