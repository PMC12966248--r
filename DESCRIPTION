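Package: infantwear
Title: Wear-Time, Cardiac and Respiration Analysis for Infant Wearable Recordings
Version: 0.1.0
Authors@R:
    person("WearAble", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multi-day wearable recordings from infants and
    toddlers: wear-state detection from joint ECG R-R interval and accelerometry
    evidence, validity-gated heart rate and heart-rate variability (SDRRI), quality
    gating and nightly summaries of nappy-mounted respiration monitor output,
    ultradian sleep-cycle period extraction by zero-phase band-pass filtering and
    peak detection, per-child reliability statistics (confidence intervals,
    coefficients of variation), paired nonparametric device comparison, and a
    seeded synthetic-cohort generator emulating all four input streams so the full
    pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
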