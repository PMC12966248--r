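# Diary/physiology timeline integration and nap-response analysis.

# A full synthetic day with a labelled nap, shared across tests.
make_day <- function(seed = 19) {
  dur <- 6 * 3600
  nap <- c(2 * 3600, 3 * 3600)
  p <- sim_profile(duration_s = dur, baseline_hr_bpm = 125, hr_jitter_ms = 25,
                   nap_windows = list(c(nap[1], nap[2], 2)),
                   movement_schedule = list(list(0, nap[1], "moving"),
                                            list(nap[1], nap[2], "still"),
                                            list(nap[2], dur, "moving")),
                   seed = seed)
  rr <- simulate_rr_stream(p)
  list(rr = rr, accel = simulate_accel(p), nap = nap,
       hr = heart_rate_series(rr),
       wear = suppressWarnings(classify_wear(rr, simulate_accel(p))))
}

test_that("build_timeline merges streams losslessly and annotates events", {
  day <- make_day()
  anchor <- "2026-01-05T08:00:00Z"
  diary <- suppressWarnings(diary_log(
    start = c("2026-01-05T10:00:00Z", "2026-01-05T12:00:00Z"),
    end = c("2026-01-05T11:00:00Z", "2026-01-05T12:30:00Z"),
    label = c("nap", "lunch"), category = c("nap", "feeding")))
  tl <- build_timeline(day$hr, day$wear, day$accel, diary, anchor = anchor)
  # lossless merge: every HR minute appears exactly once
  expect_equal(sum(!is.na(tl$minutes$hr_bpm)), sum(!is.na(day$hr$hr_bpm)))
  expect_equal(nrow(tl$minutes), length(unique(tl$minutes$minute_start_s)))
  expect_equal(nrow(tl$events), 2)
  # the nap event's mean HR is below the non-nap mean (constructed dip)
  nap_hr <- tl$events$mean_hr_bpm[1]
  non_nap <- mean(tl$minutes$hr_bpm[tl$minutes$minute_start_s < day$nap[1] |
                                      tl$minutes$minute_start_s >= day$nap[2]], na.rm = TRUE)
  expect_lt(nap_hr, non_nap)
  # empty diary -> physiology-only timeline
  tl0 <- build_timeline(day$hr, day$wear, day$accel, NULL)
  expect_null(tl0$events)
  expect_gt(nrow(tl0$minutes), 0)
})

test_that("events in gated-out gaps are annotated HR-undefined and clipping is noted", {
  day <- make_day()
  # hollow out the HR series over 12:00-13:00 relative minutes 60-120
  hr <- day$hr
  hr$hr_bpm[hr$minute_start_s >= 3600 & hr$minute_start_s < 7200] <- NA
  diary <- diary_log(start = "2026-01-05T09:10:00Z", end = "2026-01-05T09:50:00Z",
                     label = "in gap", category = "other")
  tl <- build_timeline(hr, day$wear, day$accel, diary, anchor = "2026-01-05T08:00:00Z")
  expect_true(is.na(tl$events$mean_hr_bpm[1]))
  # event beyond the recording span is clipped with a note
  diary2 <- diary_log(start = "2026-01-05T13:30:00Z", end = "2026-01-05T15:00:00Z",
                      label = "late", category = "other")
  expect_message(tl2 <- build_timeline(hr, day$wear, day$accel, diary2,
                                       anchor = "2026-01-05T08:00:00Z"),
                 "clipped")
  expect_true(tl2$events$clipped[1])
  expect_lte(tl2$events$end_s[1], max(tl2$minutes$minute_start_s) + 60)
})

test_that("disjoint streams are rejected", {
  day <- make_day()
  tiny <- accel_series(ax_mg = 0, ay_mg = 0, az_mg = 1000, sample_rate_hz = 25)
  hr_late <- day$hr
  hr_late$minute_start_s <- hr_late$minute_start_s + 1e6
  expect_error(build_timeline(hr_late, day$wear, tiny),
               "overlap", class = "infantwear_validation_error")
})

test_that("nap_response finds the constructed HR dip and HRV rise", {
  # hand-built streams: HR dips 2 SD mid-recording, HRV (interval spread)
  # triples inside the nap
  set.seed(77)
  nap <- c(7200, 10800)
  mins <- 6 * 60
  hr_vals <- 125 + rnorm(mins, 0, 2)
  in_nap_min <- seq(nap[1] / 60 + 1, nap[2] / 60)
  hr_vals[in_nap_min] <- hr_vals[in_nap_min] - 2 * sd(hr_vals)
  hr <- structure(data.frame(minute_start_s = (0:(mins - 1)) * 60,
                             hr_bpm = hr_vals, n_intervals = 120L),
                  class = c("hr_series", "data.frame"))
  wins <- 36
  sdrri <- 25 + rnorm(wins, 0, 2)
  in_nap_win <- seq(nap[1] / 600 + 1, nap[2] / 600)
  sdrri[in_nap_win] <- sdrri[in_nap_win] + 3 * sd(sdrri)
  hrv <- structure(data.frame(window_start_s = (0:(wins - 1)) * 600,
                              sdrri_ms = sdrri, n_intervals = 1200L),
                   class = c("hrv_series", "data.frame"))
  nr <- nap_response(hr, hrv, nap)
  expect_lte(nr$min_hr_z, -1)
  expect_gte(nr$max_hrv_z, 2)
  # identity: trace equal to the baseline mean gives z = 0
  hr_flat <- hr
  hr_flat$hr_bpm[in_nap_min] <- mean(hr$hr_bpm)
  expect_equal(nap_response(hr_flat, hrv, nap, hr_baseline = hr$hr_bpm)$min_hr_z, 0,
               tolerance = 1e-9)
  # window outside the recording -> error
  expect_error(nap_response(hr, hrv, c(1e6, 1e6 + 600)),
               class = "infantwear_validation_error")
  # z-scores invariant under affine rescaling of the raw series
  hr_scaled <- hr
  hr_scaled$hr_bpm <- 3 * hr$hr_bpm + 10
  expect_equal(nap_response(hr_scaled, hrv, nap)$min_hr_z, nr$min_hr_z,
               tolerance = 1e-9)
})

test_that("timeline_long emits one row per minute and variable", {
  day <- make_day()
  tl <- build_timeline(day$hr, day$wear, day$accel, NULL)
  long <- timeline_long(tl)
  expect_equal(nrow(long), 3 * nrow(tl$minutes))
  expect_setequal(unique(long$variable), c("hr_bpm", "activity_sd_mg", "wear_state"))
})
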