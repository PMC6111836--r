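Package: hrsched
Title: Energy-Aware Heart-Rate Sampling Schedules for Wearable Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns a wearer's risky hourly intervals from a few weeks of
    minute-resolution smartband heart-rate data using two-stage thresholding
    (a per-day weighted-extrema threshold followed by a training threshold
    over weekly maxima), predicts the weekday-hour slots that need
    high-frequency monitoring, schedules dual-frequency sampling (60
    measurements per hour inside predicted risk slots, 6 per hour elsewhere),
    and quantifies the Bluetooth communication energy saved under a
    per-transmission cost model. Includes gap interpolation and hourly
    aggregation for raw streams, a day-level train/validate accuracy
    procedure, and a synthetic routine generator so the whole pipeline is
    testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
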