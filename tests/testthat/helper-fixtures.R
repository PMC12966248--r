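# Shared in-code fixtures.  Everything is generated; nothing is read from disk.

# A gap-free R-R series from a vector of intervals (ms).
rr_from_intervals <- function(rr_ms, start_time = "2026-01-05T09:00:00Z") {
  rr_series(t_s = cumsum(rr_ms) / 1000, rr_ms = rr_ms, start_time = start_time)
}

# Constant-orientation accelerometry with chosen per-axis noise SD (mg).
make_accel <- function(duration_s, sd_mg = 0, rate = 25, seed = 1) {
  n <- duration_s * rate
  set.seed(seed)
  accel_series(ax_mg = rnorm(n, 0, sd_mg), ay_mg = rnorm(n, 0, sd_mg),
               az_mg = 1000 + rnorm(n, 0, sd_mg), sample_rate_hz = rate)
}

# A respiration night straight from vectors (30-s cadence).
make_night <- function(rate_bpm, autocorr = rep(0.9, length(rate_bpm)),
                       position = rep("supine", length(rate_bpm))) {
  respiration_night(t_s = seq_along(rate_bpm) * 30 - 30, resp_rate_bpm = rate_bpm,
                    autocorr = autocorr, position = position)
}

# Table of published per-child device-success proportions (usable nights and
# monitor days out of a 7-day window), used by the acceptance tests.
published_device_success <- function() {
  data.frame(
    child_id = sprintf("P%03d", 1:7),
    nappa_usable = c(1, 3, 0, 5, 2, 2, 7),
    nappa_prop = c(0.14, 0.43, 0, 0.71, 0.29, 0.29, 1),
    hr_usable = c(2, 5, 0, 3, 0, 0, 1),
    hr_prop = c(0.29, 0.71, 0, 0.43, 0, 0, 0.14)
  )
}

# Brute-force two-sided signed-rank p-value / statistic by full enumeration
# of sign assignments (independent oracle for n <= 8).
brute_force_signed_rank <- function(d, ties = c("ordinal", "average")) {
  ties <- match.arg(ties)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = if (ties == "ordinal") "first" else "average")
  T_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  sums <- vapply(0:(2^n - 1), function(m) {
    sgn <- as.integer(intToBits(m))[1:n]
    sum(r[sgn == 1])
  }, 0)
  list(statistic_T = T_obs, p_value = min(1, 2 * mean(sums <= T_obs)))
}
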