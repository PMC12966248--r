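# Gated heart-rate and HRV computation.

test_that("filter_physiological keeps the range and counts exclusions per window", {
  rr <- rr_series(t_s = c(0.5, 1.0, 3.0), rr_ms = c(500, 500, 2000),
                  check_continuity = FALSE)
  fp <- filter_physiological(rr)
  expect_equal(fp$series$beats$rr_ms, c(500, 500))
  expect_equal(fp$outside_counts$n_outside, 1)
  # all inside -> zero counts
  rr2 <- rr_from_intervals(rep(500, 100))
  expect_equal(filter_physiological(rr2)$outside_counts$n_outside, 0)
  # empty series -> empty output
  fp0 <- filter_physiological(rr_series())
  expect_equal(nrow(fp0$series$beats), 0)
  expect_equal(nrow(fp0$outside_counts), 0)
})

test_that("heart rate is 60000/mean(rr) where the 25-interval gate passes", {
  rr <- rr_from_intervals(rep(500, 120))  # one minute, 120 intervals
  hr <- heart_rate_series(rr)
  expect_equal(hr$hr_bpm[1], 120)
  # 24 intervals in the minute -> undefined
  rr24 <- rr_series(t_s = seq(2, 48, by = 2), rr_ms = rep(900, 24),
                    check_continuity = FALSE)
  hr24 <- heart_rate_series(rr24)
  expect_equal(hr24$n_intervals[1], 24)
  expect_true(is.na(hr24$hr_bpm[1]))
  # exactly 25 passes
  rr25 <- rr_series(t_s = seq(2, 50, by = 2), rr_ms = rep(900, 25),
                    check_continuity = FALSE)
  expect_false(is.na(heart_rate_series(rr25)$hr_bpm[1]))
})

test_that("synthetic hour at 130 bpm recovers the generator truth", {
  p <- sim_profile(duration_s = 3600, baseline_hr_bpm = 130, hr_jitter_ms = 20, seed = 6)
  hr <- heart_rate_series(simulate_rr_stream(p))
  expect_lt(abs(mean(hr$hr_bpm, na.rm = TRUE) - 130), 1)
})

test_that("SDRRI is the mean of 2-min sub-segment SDs under the 100-interval gate", {
  # constant intervals -> zero variability
  rr <- rr_from_intervals(rep(500, 1200))  # 10 min
  hrv <- hrv_series(rr)
  expect_equal(hrv$sdrri_ms[1], 0)
  # alternating 480/520: every 2-min sub-segment has sample SD ~20 ms
  rr2 <- rr_from_intervals(rep(c(480, 520), 600))
  hrv2 <- hrv_series(rr2)
  n_sub <- 240  # intervals per 2-min sub-segment
  expect_equal(hrv2$sdrri_ms[1], 20 * sqrt(n_sub / (n_sub - 1)), tolerance = 0.01)
  # oracle: direct SD computation per sub-segment
  b <- filter_physiological(rr2)$series$beats
  sub <- floor(b$t_s[b$t_s < 600] / 120)
  expect_equal(hrv2$sdrri_ms[1], mean(tapply(b$rr_ms[b$t_s < 600], sub, sd)),
               tolerance = 1e-9)
  # 99 intervals -> undefined
  rr99 <- rr_series(t_s = seq(3, 597, by = 6), rr_ms = rep(c(480, 520), length.out = 100)[1:100],
                    check_continuity = FALSE)
  rr99 <- rr_series(t_s = rr99$beats$t_s[1:99], rr_ms = rr99$beats$rr_ms[1:99],
                    check_continuity = FALSE)
  expect_true(is.na(hrv_series(rr99)$sdrri_ms[1]))
})

test_that("quality report coverage and flagging behave at the thresholds", {
  rr <- rr_from_intervals(rep(500, 2400))  # 20 min dense
  qr <- quality_report(rr)
  expect_equal(qr$prop_hr_coverage, 1)
  expect_equal(qr$prop_hrv_coverage, 1)
  expect_length(qr$flagged_windows, 0)
  # one window with 151 non-physiological intervals is flagged; 150 is not
  mk <- function(n_bad) {
    rr_series(t_s = seq(0.1, 599, length.out = n_bad), rr_ms = rep(100, n_bad),
              check_continuity = FALSE)
  }
  expect_equal(quality_report(mk(151))$flagged_windows, 0)
  expect_length(quality_report(mk(150))$flagged_windows, 0)
  # empty series -> undefined proportions
  qr0 <- quality_report(rr_series())
  expect_true(is.na(qr0$prop_hr_coverage))
  expect_equal(qr0$n_windows, 0)
})

test_that("no value escapes its gate and HRV coverage <= HR coverage", {
  for (seed in 1:5) {
    p <- sim_profile(duration_s = 3 * 3600, baseline_hr_bpm = 115, hr_jitter_ms = 30,
                     artefact_fraction = 0.1,
                     detach_windows = list(c(3000, 4500), c(8000, 9500)),
                     seed = seed)
    rr <- simulate_rr_stream(p)
    cfg <- analysis_config()
    hr <- heart_rate_series(rr, cfg)
    expect_true(all(is.na(hr$hr_bpm[hr$n_intervals < cfg$min_intervals_hr_minute])))
    expect_true(all(!is.na(hr$hr_bpm[hr$n_intervals >= cfg$min_intervals_hr_minute])))
    hrv <- hrv_series(rr, cfg)
    expect_true(all(is.na(hrv$sdrri_ms[hrv$n_intervals < cfg$min_intervals_hrv_window])))
    qr <- quality_report(rr, cfg)
    expect_lte(qr$prop_hrv_coverage, qr$prop_hr_coverage)
  }
})

test_that("HR and SDRRI scale correctly when intervals are scaled", {
  p <- sim_profile(duration_s = 3600, baseline_hr_bpm = 120, hr_jitter_ms = 15, seed = 10)
  rr <- simulate_rr_stream(p)
  c_fac <- 1.2
  # widen the physiological range so the scaled stream passes the same filter
  cfg <- analysis_config(rr_physio_lower_ms = 1, rr_physio_upper_ms = 5000)
  scaled <- rr_series(t_s = rr$beats$t_s * c_fac, rr_ms = rr$beats$rr_ms * c_fac,
                      check_continuity = FALSE)
  hr1 <- heart_rate_series(rr, cfg)
  hr2 <- heart_rate_series(scaled, cfg)
  # compare over minutes defined in both (time axis also stretched; use overlap)
  m <- min(sum(!is.na(hr1$hr_bpm)), sum(!is.na(hr2$hr_bpm)))
  expect_gt(m, 30)
  expect_equal(mean(hr2$hr_bpm, na.rm = TRUE) * c_fac, mean(hr1$hr_bpm, na.rm = TRUE),
               tolerance = 0.01)
  hrv1 <- hrv_series(rr, cfg); hrv2 <- hrv_series(scaled, cfg)
  expect_equal(mean(hrv2$sdrri_ms, na.rm = TRUE) / c_fac, mean(hrv1$sdrri_ms, na.rm = TRUE),
               tolerance = 0.02)
})

test_that("z-scoring uses the child baseline and propagates NAs", {
  x <- c(10, 12, NA, 14)
  z <- zscore(x)
  expect_equal(z[c(1, 2, 4)], (c(10, 12, 14) - 12) / 2)
  expect_true(is.na(z[3]))
  expect_equal(zscore(12, baseline = x), 0)  # value at the baseline mean
  expect_error(zscore(rep(5, 4)), "zero-variance", class = "infantwear_validation_error")
  expect_error(zscore(5), ">= 2 defined", class = "infantwear_validation_error")
  expect_error(zscore(rep(1, 3), child_id = "P009"), "P009")
})

test_that("a simulated 2-SD nap dip drives the minimum nap z below -1", {
  p <- sim_profile(duration_s = 8 * 3600, baseline_hr_bpm = 125, hr_jitter_ms = 25,
                   nap_windows = list(c(3 * 3600, 4 * 3600, 2)), seed = 14)
  hr <- heart_rate_series(simulate_rr_stream(p))
  hz <- zscore(hr)
  in_nap <- hr$minute_start_s >= 3 * 3600 & hr$minute_start_s < 4 * 3600
  expect_lte(min(hz$hr_z[in_nap], na.rm = TRUE), -1)
})
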