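# Reliability statistics, usability, device comparison, sensitivity sweep.

test_that("usable_units applies the 6-hour rules with a boundary below threshold", {
  rec <- child_record("A",
    hr_days = data.frame(day = 1:3, mean_hr_bpm = 120, mean_sdrri_ms = 30,
                         attached_hours = c(6, 5.9, 8)),
    nappa_nights = data.frame(night_id = 1:2, duration_h = c(6, 5.99)))
  u <- usable_units(rec)
  expect_equal(u$hr_usable, 2)     # 5.9 h is not usable
  expect_equal(u$nappa_usable, 1)  # 5.99 h is not usable; 6 h exactly is
  expect_equal(u$denominator, 7)
  # no recordings at all
  u0 <- usable_units(child_record("B"))
  expect_equal(c(u0$nappa_usable, u0$hr_usable), c(0, 0))
  expect_equal(c(u0$nappa_prop, u0$hr_prop), c(0, 0))
  expect_error(usable_units(rec, usability_rules(study_days = 0)),
               class = "infantwear_config_error")
})

test_that("relaxing a usability rule never decreases usable counts", {
  set.seed(31)
  rec <- child_record("C",
    hr_days = data.frame(day = 1:7, mean_hr_bpm = 120, mean_sdrri_ms = 30,
                         attached_hours = runif(7, 0, 12)),
    nappa_nights = data.frame(night_id = 1:7, duration_h = runif(7, 0, 12)))
  counts <- vapply(c(10, 8, 6, 4, 2), function(h)
    usable_units(rec, usability_rules(min_attached_hours = h, min_night_hours = h))$hr_usable, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("reliability_table matches hand-computed mean/CI/CV and handles n = 1", {
  rec <- child_record("D",
    hr_days = data.frame(day = 1:2, mean_hr_bpm = c(120, 126),
                         mean_sdrri_ms = c(NA, 34), attached_hours = 8),
    nappa_nights = data.frame(night_id = 1:3, duration_h = 9,
                              prop_above_autocorr = 0.5, mean_resp_rate_bpm = 25,
                              resp_rate_variance = 3,
                              ultradian_period_min = c(60, 60, 60)))
  tab <- reliability_table(rec)
  hr <- tab[tab$metric == "HR", ]
  expect_equal(hr$mean, 123)
  expect_equal(hr$cv_percent, 100 * sd(c(120, 126)) / 123)
  half <- qt(0.975, 1) * sd(c(120, 126)) / sqrt(2)
  expect_equal(c(hr$ci_low, hr$ci_high), c(123 - half, 123 + half))
  # single defined unit: mean only
  hrv <- tab[tab$metric == "HRV", ]
  expect_equal(hrv$mean, 34)
  expect_true(is.na(hrv$cv_percent) && is.na(hrv$ci_low))
  expect_equal(hrv$n_units, 1L)
  # identical units: CV exactly 0
  ult <- tab[tab$metric == "ultradian_period", ]
  expect_equal(ult$cv_percent, 0)
})

test_that("CV is invariant under positive rescaling of unit values", {
  set.seed(7)
  v <- rnorm(5, 120, 6)
  mk <- function(v) child_record("E",
    hr_days = data.frame(day = seq_along(v), mean_hr_bpm = v,
                         mean_sdrri_ms = NA_real_, attached_hours = 8))
  cv1 <- reliability_table(mk(v))$cv_percent[1]
  cv2 <- reliability_table(mk(3.7 * v))$cv_percent[1]
  expect_equal(cv1, cv2)
})

test_that("signed-rank test agrees with brute-force enumeration for n <= 8", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n), 1)
    # force occasional ties and zeros
    if (rep %% 3 == 0 && n > 2) d[2] <- d[1]
    if (rep %% 4 == 0) d[n] <- 0
    for (ties in c("ordinal", "average")) {
      got <- signed_rank_test(d, ties = ties)
      if (got$reason == "all_zero") next
      want <- brute_force_signed_rank(d, ties = ties)
      expect_equal(got$statistic_T, want$statistic_T)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    }
  }
})

test_that("signed-rank edge cases: all positive, all zero", {
  res <- signed_rank_test(c(1, 2, 3) / 7)
  expect_equal(res$statistic_T, 0)  # no negative ranks
  expect_equal(res$p_value, 2 * 1 / 8)
  res0 <- signed_rank_test(rep(0, 5))
  expect_equal(res0$reason, "all_zero")
  expect_true(is.na(res0$statistic_T))
})

test_that("compare_devices wires usable units through the test", {
  co <- simulate_cohort(3, list(c(5, 2), c(2, 5), c(3, 3)), seed = 2)
  cmp <- compare_devices(co)
  expect_equal(nrow(cmp$per_child), 3)
  expect_equal(cmp$per_child$diff, c(3, -3, 0) / 7)
  expect_equal(cmp$n_nonzero, 2)
  # identical proportions per child -> undefined statistic
  co_eq <- simulate_cohort(2, list(c(4, 4), c(2, 2)), seed = 3)
  expect_equal(compare_devices(co_eq)$reason, "all_zero")
  expect_error(compare_devices(simulate_cohort(0, list())), class = "infantwear_config_error")
})

test_that("precision_halfwidth closed form", {
  expect_equal(precision_halfwidth(0.5, 100), 1.96 * sqrt(0.25 / 100))
  expect_equal(precision_halfwidth(0, 1000), 0)
  expect_error(precision_halfwidth(1.2, 10), class = "infantwear_config_error")
  expect_error(precision_halfwidth(0.5, 0), class = "infantwear_config_error")
})

test_that("threshold sweep: identity at defaults, monotone in movement threshold", {
  p <- sim_profile(duration_s = 7200, baseline_hr_bpm = 120, hr_jitter_ms = 15,
                   artefact_fraction = 0.02,
                   detach_windows = list(c(0, 3600)),
                   movement_schedule = list(list(0, 3600, "moving"),
                                            list(3600, 7200, "still")),
                   seed = 44)
  rr <- simulate_rr_stream(p)
  acc <- simulate_accel(p, moving_sd_mg = 14)
  night <- simulate_respiration_night(resp_profile(8 * 3600, seed = 44, dropout_fraction = 0.2))
  cfg <- analysis_config()
  one <- threshold_sensitivity(rr, acc, night, cfg,
                               sweep = list(movement_sd_threshold_mg = 13))
  states <- classify_wear(rr, acc, cfg)
  ws <- wear_summary(states, rr, cfg)
  expect_equal(one$wear_attached_s, ws$wear_attached_s)
  expect_equal(one$wear_detached_s, ws$wear_detached_s)
  expect_equal(one$prop_above_autocorr, mean(quality_mask(night, cfg)))
  swept <- threshold_sensitivity(rr, acc, NULL, cfg,
                                 sweep = list(movement_sd_threshold_mg = c(10, 13, 16)))
  expect_true(all(diff(swept$wear_detached_s) <= 0))
  expect_error(threshold_sensitivity(rr, acc, NULL, cfg, sweep = list()),
               class = "infantwear_config_error")
  expect_error(threshold_sensitivity(rr, acc, NULL, cfg, sweep = list(bogus = 1)),
               class = "infantwear_config_error")
})

test_that("cohort_summary rolls up per-child counts", {
  co <- simulate_cohort(2, list(c(3, 1), c(0, 4)), seed = 5)
  cs <- cohort_summary(co)
  expect_equal(cs$nights_recorded, c(3, 0))
  expect_equal(cs$nights_usable, c(3, 0))
  expect_equal(cs$hr_days_usable, c(1, 4))
  # attached hours: usable days carry 8 h, others 2 h over a 7-day window
  expect_equal(cs$total_attached_h, c(1 * 8 + 6 * 2, 4 * 8 + 3 * 2))
})
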