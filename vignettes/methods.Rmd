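---
title: "Risk-interval learning and duty-cycled sampling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-interval learning and duty-cycled sampling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrsched)
```

## The problem

A wrist band measuring heart rate once a minute and shipping every reading
over Bluetooth spends most of its communication budget on hours in which
nothing noteworthy happens. For a wearer with a stable weekly routine, the
hours of elevated heart rate — exercise, exertion — recur at predictable
weekday-hour slots. `hrsched` learns those slots and samples densely only
inside them, trading a 10× lower measurement rate elsewhere for a large cut
in transmission count while the wearer keeps being monitored continuously.

## The two-stage model

**Stage 1 — daily threshold.** Each day is summarised by its extrema
$R_{\max}$ and $R_{\min}$ and thresholded at

$$t \;=\; \tfrac{2}{3} R_{\max} + \tfrac{1}{3} R_{\min}.$$

An hour $[h, h{+}1)$ is a *risky range* of that day when its hourly **mean**
bpm strictly exceeds $t$. The 2:1 weighting toward the maximum is the point:
an unweighted midpoint would flag every moderately active hour, which is
useless both clinically (no elevated risk) and energetically (too many
high-frequency hours).

**Stage 2 — training threshold.** Daily thresholds adapt to each day's
range, so a quiet day can still flag hours that are unremarkable for the
wearer overall. The second stage compares across the training window: with
weekly maxima $M_1, M_2, M_3$ of the last three weeks and ratio $R_t$,

$$T_t \;=\; \overline{M} \cdot R_t, \qquad \overline{M} = \tfrac{1}{3}\sum_w M_w .$$

Only risky ranges whose mean strictly exceeds $T_t$ enter the prediction.
The prediction is the **union** over the three weeks of surviving ranges,
keyed by `(weekday, hour)`. Union rather than intersection is a deliberate
design choice: a genuine routine observed in a single training week (a
fortnightly activity, a missed week of wear) should still be monitored;
intersection would discard any slot not repeated in all three weeks, and in
the bundled example record it would reduce the four-slot prediction to a
single Thursday slot. The price of the union is a more conservative — more
energy-hungry — schedule, which we consider the right failure mode for a
safety application.

**Recalculation.** `recalculate_routines()` re-runs the window weekly in a
mark-and-sweep form: slots confirmed by the new window are (re-)marked,
unconfirmed carried-over slots are swept. Algebraically this equals
`build_prediction()` on the latest window — the formulation exists because
it makes the adaptation property explicit, and a property test asserts the
equivalence. A dropped routine thus leaves the schedule after the three-week
window no longer contains it.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `ratio` ($R_t$) | 0.8 | – | fraction of the mean weekly maximum a range must clear; raising it monotonically shrinks the prediction (property-tested) |
| `high_freq` | 60 | measurements/h | sampling inside risk slots (one per minute) |
| `low_freq` | 6 | measurements/h | sampling elsewhere (one per 10 min, at minutes 0, 10, ..., 50; the phase is unspecified by the scheme, zero phase is chosen) |
| `e_conn` | 0.03 | Ws | average cost of one BLE transmission, bounded to [0.01, 0.05] |
| `e_range` | (0.01, 0.05) | Ws | per-transmission fluctuation range for the stochastic simulator |

With constant per-transmission cost the percentage reduction is scale
invariant in `e_conn` and depends only on the weekly risk-hour count $k$:

$$\mathrm{reduction}(k) = 100\!\left(1 - \frac{60k + 6(168-k)}{60 \cdot 168}\right),$$

capped at 90% ($k = 0$). The test suite checks the closed form at
$k \in \{0, 4, 12, 168\}$ and across `e_conn` values.

## Comparisons, precision, degenerate inputs

* All threshold comparisons are **strict** (`>`). A consequence worth
  knowing: a range whose mean equals or sits just below $T_t$ is excluded
  even when rounding to two decimals would tie it — in the bundled example's
  second window a 98.00-bpm range falls 0.40 below the 98.40 threshold and
  is excluded, which is why that prediction has 11 unit slots rather than
  12. Display formatting rounds bpm to 2 decimals; every comparison uses
  full precision, avoiding any dependence on rounding order.
* $\overline{M}$ is the plain arithmetic mean of the weekly maxima; no
  weighting across weeks is applied.
* Hour buckets are half-open $[h, h{+}1)$ in local clock time (timestamps
  are taken as local: routines like sleep are local-time phenomena; the
  device's notion of time is passed through untouched). A sample at
  exactly midnight belongs to the starting day.
* Hours with no data produce no aggregate and no risky range — absence of
  evidence is never treated as 0 bpm. Multi-hour activity is represented as
  unit `(weekday, hour)` slots, which keeps the scheduler's and the energy
  model's arithmetic well defined.
* Degenerate inputs: a constant day has $t = $ the constant and flags
  nothing (strict comparison); an empty day cannot be thresholded and
  raises an insufficient-data error; duplicate timestamps are an error
  rather than averaged; bpm outside (0, 300) is rejected as corrupt.
* Gap filling is linear interpolation on the 1-minute grid between a day's
  first and last sample only — no extrapolation, no filling across
  midnight. Interpolation is idempotent, bounded by the flanking samples,
  and cannot create new extrema (all property-tested). The reported missing
  fraction is filled grid points over total grid points.

## Day-level validation procedure

When only a few consecutive days per subject are available, a day-level
variant is used: on the training day, hours whose hourly **maximum**
exceeds the daily threshold are marked (with a single day and no training
threshold to prune noise, the maximum is the more sensitive statistic; a
dedicated fixture in the tests demonstrates the max/mean distinction).
Scoring against the next day counts, over the hours observed on **both**
days, those whose risk status agrees — quiet-quiet agreement counts exactly
like risky-risky, since both mean the schedule would have sampled at the
correct rate. Varying data availability therefore varies the denominator
(23 shared hours gives steps of 1/23, etc.). Cohort summaries report the
mean and the sample (n−1) standard deviation of per-user accuracies.

## The synthetic generator

`routine_profile()` + `generate_day()`/`generate_weeks()` emulate the
statistical structure the method relies on:

* piecewise-constant daily means — sleep (00:00–08:00 at 65 bpm by
  default) and a waking level at the midpoint of the 60–100 bpm band;
* a brief midday excursion to the top of the waking band (ordinary
  exertion such as a brisk walk). This matters: it keeps a quiet day's
  maximum well above its hourly means, as in real traces, so that the
  daily threshold clears every hourly mean and a routine without exercise
  yields an empty prediction. Without it a perfectly flat day would have
  mean = max and self-flag;
* exercise bouts at fixed weekday-hour slots: a 10-minute linear ramp up
  to the peak, the peak held through the bout, then a 30-minute linear
  decay back to baseline;
* independent Gaussian noise per minute (sd 3 bpm by default, matching the
  few-bpm wobble of resting traces), truncated to the physiological band
  40–200 bpm;
* uniform random deletion of minutes at `missing_rate` (default 0.05,
  within the 3–9% dropout range seen on worn devices; gaps on real
  hardware come from unmodelled causes — dirty glass, loose fit — so
  uniformity is an assumption, not a claim).

Everything is deterministic given the profile seed. At zero noise the
pipeline recovers the generating exercise slots exactly, and with sd 3 bpm
the suite requires ≥95% slot recovery over 50 seeded replicates. What the
generator does **not** emulate: beat-to-beat variability, circadian drift
within the waking period, autocorrelated dropout, and day-to-day amplitude
variation of real exercise — so green tests demonstrate correctness of the
algorithmic pipeline, not field performance on real wearers.

## Problem sizes in the test suite

The property tests run the full pipeline on generated data at sizes chosen
to exercise every code path while keeping the suite quick: 100 random
3-week datasets for the brute-force equivalence check (every hourly mean,
threshold and comparison re-derived independently in base R), 50 noisy
replicates for slot recovery, and 1000 seeds for the Monte-Carlo check that
the fluctuating-cost simulator is unbiased (its mean daily total must fall
within three standard errors of the closed form at the 0.03 Ws midpoint;
with a degenerate cost range the simulator must equal the deterministic
report exactly).

## Known limitations

* Slots are statistical flags on one wearer's routine, not clinical risk
  assessments.
* The energy model covers communication only — one transmission per
  measurement, no batching, no sensor or processing energy, no Bluetooth
  protocol states or battery discharge curve.
* A three-week window adapts with a three-week lag; a wearer whose routine
  changes faster is under-covered in the interim (mitigated by the 6/h
  floor — monitoring never stops).
* The day-level validation compares adjacent calendar days, which may have
  genuinely different routines (weekday vs weekend); its accuracy is a
  property of the wearer's regularity as much as of the method.
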