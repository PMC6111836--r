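#' Bluetooth per-transmission energy model
#'
#' Each heart-rate measurement costs one Bluetooth Low Energy transmission.
#' A transmission costs between 0.01 and 0.05 watt-seconds depending on
#' conditions; 0.03 Ws is used as the average for deterministic reports,
#' and the full range feeds the fluctuating-cost simulator.
#'
#' @param e_conn average cost of one transmission, Ws, in \[0.01, 0.05\].
#' @param e_range length-2 cost range for stochastic simulation, Ws.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(e_conn = 0.03, e_range = c(0.01, 0.05)) {
  if (!is.finite(e_conn) || e_conn < 0.01 || e_conn > 0.05) {
    abort_validation("`e_conn` must lie in [0.01, 0.05] Ws per transmission")
  }
  if (length(e_range) != 2 || any(!is.finite(e_range)) ||
      e_range[1] > e_range[2] || e_range[1] < 0.01 || e_range[2] > 0.05) {
    abort_validation("`e_range` must be an ordered pair within [0.01, 0.05] Ws")
  }
  structure(list(e_conn = e_conn, e_range = as.double(e_range)),
            class = "energy_model")
}

as_energy_model <- function(model) {
  if (inherits(model, "energy_model")) return(model)
  if (is.numeric(model) && length(model) == 1) return(energy_model(e_conn = model))
  abort_argument("`model` must be an energy_model or a single e_conn value")
}

#' Turn a prediction into a dual-frequency weekly sampling plan
#'
#' Every predicted risk slot is sampled at high frequency (one measurement
#' per minute); every other hour of the week at low frequency (one per 10
#' minutes, i.e. at minutes 0, 10, 20, 30, 40, 50) — monitoring never
#' stops, it only slows down. The plan covers all 168 weekday-hour slots.
#'
#' @param pred an `hr_prediction` (or any tibble with `weekday`, `hour`).
#' @param high_freq measurements per hour inside risk slots, default 60.
#' @param low_freq measurements per hour elsewhere, default 6.
#' @return A 168-row tibble of class `sampling_plan`: `weekday` (0--6),
#'   `hour` (0--23), `freq` (measurements per hour).
#' @export
build_plan <- function(pred, high_freq = 60, low_freq = 6) {
  if (!(high_freq > low_freq && low_freq > 0)) {
    abort_validation("need `high_freq` > `low_freq` > 0")
  }
  plan <- tibble::tibble(
    weekday = rep(0:6, each = 24L),
    hour = rep(0:23, times = 7L),
    freq = low_freq
  )
  if (!is.null(pred) && nrow(pred) > 0) {
    risky <- paste(pred$weekday, pred$hour) |> unique()
    plan$freq[paste(plan$weekday, plan$hour) %in% risky] <- high_freq
  }
  structure(plan, class = c("sampling_plan", class(plan)))
}

new_energy_report <- function(per_hour, total, baseline_total) {
  structure(
    list(
      per_hour = per_hour,
      total = total,
      baseline_total = baseline_total,
      reduction_pct = 100 * (baseline_total - total) / baseline_total
    ),
    class = "energy_report"
  )
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(
    "<energy_report> %.2f Ws vs always-on %.2f Ws: %.2f%% reduction (%d hour slots)\n",
    x$total, x$baseline_total, x$reduction_pct, nrow(x$per_hour)))
  invisible(x)
}

#' Weekly communication energy under a sampling plan
#'
#' Every measurement is one transmission, so an hour's cost is
#' `freq * e_conn` Ws; the always-on baseline measures 60 times in each of
#' the week's 168 hours.
#'
#' @param plan a [build_plan()] result.
#' @param model an [energy_model()] (or a bare `e_conn` value).
#' @return An `energy_report`: `per_hour` tibble (`weekday`, `hour`, `ws`,
#'   `ws_baseline`), `total`, `baseline_total`, `reduction_pct`.
#' @export
weekly_energy <- function(plan, model = energy_model()) {
  model <- as_energy_model(model)
  per_hour <- tibble::tibble(
    weekday = plan$weekday,
    hour = plan$hour,
    ws = plan$freq * model$e_conn,
    ws_baseline = 60 * model$e_conn
  )
  new_energy_report(per_hour, sum(per_hour$ws), sum(per_hour$ws_baseline))
}

#' Daily communication energy under a sampling plan
#'
#' @inheritParams weekly_energy
#' @param weekday integer 0--6 (Monday = 0) selecting the plan's day.
#' @return An `energy_report` over that day's 24 hour slots; the baseline is
#'   `24 * 60 * e_conn`.
#' @export
daily_energy <- function(plan, weekday, model = energy_model()) {
  model <- as_energy_model(model)
  day <- plan[plan$weekday == weekday, , drop = FALSE]
  if (nrow(day) != 24) {
    abort_argument("`weekday` must select 24 hour slots of the plan (0..6)")
  }
  per_hour <- tibble::tibble(
    weekday = day$weekday,
    hour = day$hour,
    ws = day$freq * model$e_conn,
    ws_baseline = 60 * model$e_conn
  )
  new_energy_report(per_hour, sum(per_hour$ws), sum(per_hour$ws_baseline))
}

#' Simulate a day's consumption with fluctuating transmission costs
#'
#' Real per-connection costs fluctuate; here each transmission's cost (for
#' the plan and for the always-on control alike) is drawn independently and
#' uniformly from the model's `e_range`. The same seed reproduces the
#' identical report bit for bit.
#'
#' @inheritParams daily_energy
#' @param seed integer seed for the draws.
#' @return An `energy_report` with stochastic `ws` / `ws_baseline` per hour.
#' @export
simulate_fluctuating_consumption <- function(plan, weekday, model = energy_model(),
                                             seed = 1L) {
  model <- as_energy_model(model)
  day <- plan[plan$weekday == weekday, , drop = FALSE]
  if (nrow(day) != 24) {
    abort_argument("`weekday` must select 24 hour slots of the plan (0..6)")
  }
  day <- day[order(day$hour), , drop = FALSE]
  a <- model$e_range[1]
  b <- model$e_range[2]
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ws <- vapply(day$freq, function(f) sum(runif(f, a, b)), double(1))
  ws_baseline <- vapply(day$freq, function(f) sum(runif(60, a, b)), double(1))
  per_hour <- tibble::tibble(
    weekday = day$weekday, hour = day$hour,
    ws = ws, ws_baseline = ws_baseline
  )
  new_energy_report(per_hour, sum(ws), sum(ws_baseline))
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Percentage energy reduction relative to an always-on baseline
#'
#' @param baseline baseline consumption, Ws, > 0.
#' @param total consumption under the plan, Ws, `<= baseline` (a duty-cycled
#'   plan can never transmit more than always-on).
#' @return `100 * (baseline - total) / baseline`.
#' @export
reduction_pct <- function(baseline, total) {
  if (any(baseline <= 0)) abort_argument("`baseline` must be positive")
  if (any(total > baseline)) {
    abort_argument("`total` cannot exceed the always-on baseline")
  }
  100 * (baseline - total) / baseline
}

#' Write an energy report's per-hour table as TSV
#'
#' Columns `day, hour, ws_approach, ws_baseline` — the data behind
#' consumption-versus-time comparisons of plan and control.
#'
#' @param report an `energy_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(report, path) {
  out <- tibble::tibble(
    day = WEEKDAY_NAMES[report$per_hour$weekday + 1L],
    hour = report$per_hour$hour,
    ws_approach = report$per_hour$ws,
    ws_baseline = report$per_hour$ws_baseline
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a sampling plan as JSON
#'
#' @param plan a `sampling_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(
    list(slots = tibble::as_tibble(plan)[c("weekday", "hour", "freq")]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
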