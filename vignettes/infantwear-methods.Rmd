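---
title: "Methods: wear-state, gated cardiac metrics, ultradian cycles and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wear-state, gated cardiac metrics, ultradian cycles and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantwear)
```

`infantwear` processes device-level exports from two infant wearables — a
chest-worn ECG/accelerometry monitor emitting R–R intervals, and a
nappy-cover sleep monitor emitting respiration rate with a per-sample
autocorrelation quality score — into wear-time, heart-rate, heart-rate
variability, respiration and reliability summaries. This vignette is the
package's own account of the method: the models and their assumptions, every
tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## 1. Wear-state model

Multi-day home recordings from young children contain three regimes that
must be separated before any physiology is reported:

* **worn and attached** — electrodes connected, heartbeat present;
* **worn but detached** — the device is on the body (it moves with the
  child) but the electrodes have disconnected, so there is no ECG;
* **not worn** — no heartbeat and no persistent movement.

Each contiguous, half-open 10-min window `[t, t + 600 s)` (0-based seconds
since recording start) is classified by a two-stage rule:

1. if the window contains at least `min_beats_worn` (default **1**) R–R
   interval inside the physiological range, it is `worn_attached`;
2. otherwise, if the sample SD of the acceleration vector magnitude
   `sqrt(ax² + ay² + az²)` over the window exceeds
   `movement_sd_threshold_mg` (default **13 mg**), it is `worn_detached`;
3. otherwise `not_worn`. A beat-free window with no accelerometry coverage
   is `not_worn` with a data-gap warning.

Design notes. "Detectable heartbeat" is operationalised as ≥ 1 physiological
interval — the weakest faithful reading, and configurable. "Persistent
movement" is a single SD over the whole window rather than per-epoch voting:
the simplest reading of a windowed SD-of-VM threshold, also configurable.
The SD uses the `n − 1` denominator, the convention used throughout the
package for small-sample physiological variability; switching to the
population form is a one-line change and the difference is below 0.1% at
window sample counts (≥ 600 samples at 25 Hz down-sampled cadences).

The wear summary rolls windows up: wear periods are maximal runs of windows
not `not_worn`; accidental detachments are `worn_attached → worn_detached`
transitions; the error rate is the count of non-physiological intervals
during attached windows per attached minute.

## 2. Physiological range and cardiac gating

All cardiac metrics see only intervals inside
`[rr_physio_lower_ms, rr_physio_upper_ms]`, default **[250, 1000] ms**
(240 bpm down to 60 bpm). This default is appropriate for infants and
toddlers but is deliberately a configuration value, prominently flagged: for
other populations it must be changed. An interval belongs to the segment
containing its beat's **end** time — one unambiguous rule for boundary
beats.

* **Heart rate**: per 1-min segment with at least
  `min_intervals_hr_minute = 25` physiological intervals,
  `HR = 60000 / mean(rr_ms)`; otherwise undefined (`NA`). The gate is
  absolute: no value is ever emitted from a failing segment.
* **HRV (SDRRI)**: per 10-min window with at least
  `min_intervals_hrv_window = 100` intervals, the sample SD of the intervals
  is computed in each 2-min sub-segment (`hrv_subsegment_s = 120`,
  minimum `min_subsegment_intervals = 2`), and the window's SDRRI is the
  arithmetic mean of the defined sub-segment SDs. Averaging the five
  sub-segment SDs (the SDNN-index convention) is an interpretation: the
  definition of a per-2-min SD inside a 10-min reporting window does not say
  how the five values combine. The per-sub-segment values are retained in
  an attribute so any other aggregation can be applied.
* **Coverage**: the proportion of 10-min windows with at least
  `min_intervals_hr_coverage = 50` (HR) or 100 (HRV) physiological
  intervals; windows with more than `nonphysio_limit_per_window = 150`
  non-physiological intervals are flagged. Since the HRV gate is strictly
  stricter, HRV coverage ≤ HR coverage always holds.
* **Z-scores**: nap analyses express HR/HRV as
  `(x − mean(baseline)) / sd(baseline)` where the baseline is the child's
  own defined values. The default baseline is all defined values of the
  recording (configurable to any explicit vector, e.g. across days):
  whether such baselines should span one recording or all of a child's days
  is not externally fixed, so the whole-recording default is the least
  assumption-laden choice. A zero-variance or < 2-point baseline is an
  error naming the child.

## 3. Respiration quality and nightly summaries

A respiration sample passes quality control iff its autocorrelation is
**strictly greater than** `autocorr_threshold = 0.35` — strict, to match the
"> 0.35" reporting convention. Nightly summaries report the mean and sample
variance of the rate over passing samples only, the passing proportion, the
recording duration, and sleeping-position fractions over all samples.
Nightly spread is reported as a variance; the SD is derivable, and which of
the two the original figures show is not stated.

## 4. Ultradian cycle extraction

The 30–120-min oscillation of respiration rate during sleep reflects
sleep-cycle structure. The pipeline, per night:

1. **Grid**: quality-passing samples are linearly interpolated onto a
   uniform 1-min grid (`grid_step_s = 60`). Gaps up to
   `gap_bridge_s = 600 s` are bridged; the night is split at longer gaps and
   segments shorter than twice the lower band period are dropped. The gap
   policy is invented (missing-data handling in cyclic analysis is never
   described for the real recordings) and is therefore configurable.
2. **Detrend**: the night median (over passing samples) is removed — robust
   to the skewed bursts that contaminate a mean.
3. **Band-pass**: a Butterworth filter of analog order `filter_order = 2`
   (doubled by the band-pass transformation), designed by bilinear
   transform for the pass-band corresponding to 30–120-min periods, applied
   forward–backward (zero phase) with odd-reflection padding and
   steady-state initial conditions. Zero phase matters because the period
   estimate comes from peak *times*; a causal filter would bias them. The
   implementation was cross-checked coefficient-for-coefficient and
   output-for-output against a reference DSP library during development,
   and the tests assert the behavioural contract (unit pass-band gain,
   out-of-band attenuation, preserved peak positions).
4. **Peaks**: local maxima with minimum separation equal to the lower band
   period (30 min) and topographic prominence at least
   `peak_prominence_sd = 0.5` times the band-passed SD.
5. **Period**: with at least 3 peaks and 2 within-segment inter-peak
   intervals, the period is the mean inter-peak interval — matching a
   peak-marking presentation rather than a spectral argmax.
   `ultradian_spectral_check()` provides the periodogram cross-check as a
   diagnostic.

**Noise guard.** Band-passing white noise always produces in-band wiggles
whose peaks clear any threshold expressed relative to the *band-passed* SD,
so prominence alone cannot reject a night that contains no cycle. The
period is therefore additionally undefined (reason `low_band_power`) unless
`sd(band-passed) ≥ band_power_ratio_min × sd(median-removed input)` with
`band_power_ratio_min = 0.4`. The margins are structural, not tuned: white
noise concentrates only ≈ 25% of its SD in this narrow band (ratio ≈ 0.26),
while a sinusoid at amplitude-SNR 2 yields ≈ 0.8. In simulation this
rejects 100% of noise-only nights while leaving recovery of injected
40/65/90/110-min periods at ≤ 2% median error.

Every undefined result carries a reason code (`no_quality_data`,
`too_short`, `low_band_power`, `too_few_peaks`, `period_out_of_band`), and a
defined period always lies inside the configured band.

## 5. Reliability, usability and device comparison

* **Reliability**: per child and metric (daily mean HR, daily mean SDRRI,
  nightly ultradian period), the across-unit mean, t-based 95% CI
  (`mean ± t(0.975, n−1)·SD/√n`) and CV% (`100·SD/mean`). With one unit the
  mean is reported and CI/CV are `NA`; with none, everything is. The
  t-based CI is a documented convention: published intervals of this kind
  are not always reconstructible from printed means and CVs, so no attempt
  is made to reverse-engineer a different construction.
* **Usability**: a monitor day is usable with ≥ 6 attached hours; a night
  with ≥ 6 recorded hours; proportions use the study window (default 7
  days) as denominator. The source tables report usable counts without
  printing their rule, so these thresholds are explicit configuration
  (`usability_rules()`), and table-level acceptance tests inject published
  counts directly rather than re-deriving them.
* **Device comparison**: per child, `diff = nappa_prop − hr_prop`; zero
  differences are dropped; absolute differences are ranked; the statistic
  `T` is the smaller of the positive/negative signed-rank sums, with the
  exact subset-sum null distribution over the realized ranks for `n ≤ 25`
  (normal approximation with continuity correction beyond). The published
  analysis calls this a "rank sum" test but describes a one-sample test of
  paired differences against zero, i.e. the signed-rank test; the package
  implements the latter under the accurate name. Tie handling is explicit:
  `ordinal` (first-occurrence) ranking reproduces the published `T = 3`
  (p = 0.156 ≈ 0.16) on the published proportions, while `average` ranking
  gives 3.5. Both modes are shipped; neither is silently preferred.
* **Precision planning**: `precision_halfwidth(p, n) = 1.96·sqrt(p(1−p)/n)`,
  the half-width of the normal-approximation 95% interval for a proportion
  — 0.098 at `n = 100`, 0.185 at `n = 28` (consistent with a "19%
  precision" planning statement if the planning unit count was 28, which is
  not recoverable from the main text).
* **Sensitivity**: `threshold_sensitivity()` re-runs the wear, quality and
  respiration summaries over a grid of configuration overrides and returns
  a long table, e.g. confirming that worn-detached time is non-increasing
  in the movement threshold.

## 6. The synthetic generator: what it emulates, and what it does not

No machine-readable recordings accompany the source study, so the generator
is a *stated world* with the statistical structure the pipeline assumes:

* **R–R streams**: clean intervals `60000/hr(t)` plus Gaussian jitter
  (default 15 ms); `hr(t)` follows a baseline with smooth nap dips
  (trapezoidal, 5-min ramps) whose depth is expressed in units of the
  minute-level HR SD implied by the jitter (delta-method approximation,
  floored at 0.5 bpm) so that a "2-SD nap" lands near z = −2 by
  construction. Artefact beats are drawn uniformly from
  `(0, lower) ∪ (upper, 3000) ms` — unambiguously non-physiological, so the
  150-per-window rule is exercisable. Detachment gaps contain no beats; the
  first beat after a gap carries a single bridging interval equal to the
  elapsed gap, as a Holter R-peak stream would emit, which preserves the
  conservation identity (sum of intervals = last − first beat time) and is
  invisible to every gated metric.
* **Accelerometry**: 25 Hz, gravity on one axis, per-axis Gaussian noise by
  movement state (moving 50 mg, still 5 mg, off-body 1.5 mg) so windows land
  clearly on the intended side of the 13 mg threshold.
* **Respiration nights**: 30-s cadence,
  `base + A·sin(2πt/period) + noise`, with dropout samples assigned
  autocorrelations below the 0.35 threshold and the rest above it; defaults
  (25 bpm base, 65-min period, 2 bpm amplitude, 1 bpm noise) are realistic
  orders of magnitude for infant sleep.
* **Cohorts**: per-child usable-unit counts are planted exactly (usable
  days carry 8 attached hours, others 2; usable nights 9 h), so
  table-logic code paths can be exercised against known inputs.

All randomness flows from one explicit seed per profile through an
RNG-state-preserving wrapper; identical profiles give byte-identical
serialised output.

What the generator does **not** emulate: real ECG morphology or detector
behaviour, biomechanically realistic accelerometry (carrying, pram rides),
autocorrelated respiration noise, position-dependent signal quality, or
parent behaviour. A green synthetic test therefore establishes that the
pipeline implements its stated rules and recovers planted structure — not
that the devices themselves perform to any standard on real children.

## 7. Degenerate inputs and numerical choices

* Empty series, empty windows and beat-free nights produce typed empty
  results or `NA` with reason codes, never silent zeros.
* Windows are half-open `[t, t + w)`; durations sum exactly to the
  recording length (partition property, tested).
* Readers never silently drop rows: malformed rows are errors naming the
  file line; unknown columns are warnings; unknown categorical labels map
  to the open-world escape (`unknown` position, `other` diary category)
  with a warning.
* CSV round-trips are exact well below the declared 1 ms / 0.1 mg
  precision (6 decimal places written).
* The exact signed-rank distribution is computed by subset-sum dynamic
  programming over doubled ranks (so average-rank ties stay integral), and
  matches full enumeration for `n ≤ 8` in the tests.

## 8. Known limitations

* The physiological R–R range, the usability rules and the ultradian gap
  policy are defensible defaults, not measured constants; conclusions
  sensitive to them should use `threshold_sensitivity()`.
* The period estimator reports a single mean inter-peak interval per night;
  within-night period drift is not modelled.
* EDF ingestion of native Holter exports is out of scope here; the
  canonical CSV formats are the interchange layer.
* The CLI reads JSON scenario configs only (no YAML parser in the target
  environment).
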