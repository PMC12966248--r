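# Quality gating, nightly summaries and ultradian sleep-cycle extraction for
# the respiration-monitor stream.

#' Respiration quality mask
#'
#' A sample passes quality control iff its autocorrelation is strictly
#' greater than the threshold (default 0.35), matching the reporting
#' convention "autocorrelation > 0.35".
#'
#' @param night a [respiration_night()].
#' @param cfg an [analysis_config()].
#' @return Logical vector, one element per sample.
#' @examples
#' n <- respiration_night(t_s = c(0, 30), resp_rate_bpm = c(24, 25),
#'                        autocorr = c(0.36, 0.35), position = c("supine", "supine"))
#' quality_mask(n)  # TRUE FALSE
#' @export
quality_mask <- function(night, cfg = NULL) {
  cfg <- as_config(cfg)
  stopifnot(inherits(night, "respiration_night"))
  night$samples$autocorr > cfg$autocorr_threshold
}

#' Nightly respiration summary
#'
#' Mean and sample variance of the respiration rate over quality-passing
#' samples, recording duration, proportion of samples above the
#' autocorrelation threshold, and the distribution of sleeping positions over
#' all samples.
#'
#' @param night a [respiration_night()].
#' @param cfg an [analysis_config()].
#' @param night_id optional identifier carried into the summary.
#' @return An object of class `night_summary`: `night_id`,
#'   `recording_duration_s`, `prop_above_autocorr`, `mean_resp_rate_bpm`,
#'   `resp_rate_variance` (both `NA` when no sample passes),
#'   `position_fractions` (named numeric summing to 1 over observed samples),
#'   `n_samples`.
#' @export
night_summary <- function(night, cfg = NULL, night_id = NA) {
  cfg <- as_config(cfg)
  stopifnot(inherits(night, "respiration_night"))
  s <- night$samples
  pass <- quality_mask(night, cfg)
  pos_frac <- if (nrow(s)) {
    tab <- table(factor(s$position, levels = POSITION_LEVELS))
    as.numeric(tab) / nrow(s)
  } else {
    rep(NA_real_, length(POSITION_LEVELS))
  }
  names(pos_frac) <- POSITION_LEVELS
  structure(list(
    night_id = night_id,
    recording_duration_s = if (nrow(s) > 1L) max(s$t_s) - min(s$t_s) else 0,
    prop_above_autocorr = if (nrow(s)) mean(pass) else NA_real_,
    mean_resp_rate_bpm = if (any(pass)) mean(s$resp_rate_bpm[pass]) else NA_real_,
    resp_rate_variance = if (sum(pass) > 1L) var(s$resp_rate_bpm[pass]) else NA_real_,
    position_fractions = pos_frac,
    n_samples = nrow(s)
  ), class = "night_summary")
}

#' @export
print.night_summary <- function(x, ...) {
  cat(sprintf("<night_summary> %s: %.1f h, %.0f%% above autocorr threshold, mean rate %s bpm\n",
              x$night_id, x$recording_duration_s / 3600,
              100 * (x$prop_above_autocorr %||% NA),
              if (is.na(x$mean_resp_rate_bpm)) "NA" else sprintf("%.1f", x$mean_resp_rate_bpm)))
  invisible(x)
}

#' Extract the ultradian sleep-cycle period from a respiration night
#'
#' Pipeline: (1) quality-passing samples are interpolated onto a uniform
#' 1-min grid, bridging gaps up to 10 min and splitting the night at longer
#' gaps; (2) the night median is removed; (3) a zero-phase Butterworth
#' band-pass isolates the 30--120-min-period component; (4) peaks are
#' detected with minimum separation equal to the lower band period and
#' prominence at least `peak_prominence_sd` times the band-passed SD;
#' (5) with at least 3 peaks (and 2 within-segment intervals), the period is
#' the mean inter-peak interval.
#'
#' A defined period additionally requires the band-passed SD to reach
#' `band_power_ratio_min` times the SD of the median-removed input: a
#' narrow-band filter always produces wiggles, so without this guard a night
#' of pure noise would often yield a spurious in-band "period".
#'
#' @param night a [respiration_night()].
#' @param cfg an [analysis_config()].
#' @return An object of class `ultradian_result`: `period_min` (`NA` when
#'   undefined), `peak_times_s`, `n_peaks`, `band_min`, and `reason` (one of
#'   `"ok"`, `"no_quality_data"`, `"too_short"`, `"low_band_power"`,
#'   `"too_few_peaks"`, `"period_out_of_band"`).
#' @examples
#' p <- resp_profile(duration_s = 8 * 3600, ultradian_period_min = 65,
#'                   ultradian_amplitude_bpm = 2, noise_sd_bpm = 1, seed = 3)
#' ultradian_cycle(simulate_respiration_night(p))
#' @export
ultradian_cycle <- function(night, cfg = NULL) {
  cfg <- as_config(cfg)
  stopifnot(inherits(night, "respiration_night"))
  band_s <- cfg$ultradian_period_band_min * 60
  result <- function(period, peaks, reason) {
    structure(list(period_min = period, peak_times_s = peaks,
                   n_peaks = length(peaks), band_min = cfg$ultradian_period_band_min,
                   reason = reason),
              class = "ultradian_result")
  }
  s <- night$samples[quality_mask(night, cfg), , drop = FALSE]
  if (nrow(s) < 2L) return(result(NA_real_, numeric(0), "no_quality_data"))
  if (max(s$t_s) - min(s$t_s) < 2 * band_s[1])
    return(result(NA_real_, numeric(0), "too_short"))
  night_median <- median(s$resp_rate_bpm)
  # Split at quality gaps longer than the bridge limit.
  seg_id <- cumsum(c(0, diff(s$t_s) > cfg$gap_bridge_s))
  fs <- 1 / cfg$grid_step_s
  filt <- butter_bandpass(cfg$filter_order,
                          w_low = (1 / band_s[2]) / (fs / 2),
                          w_high = (1 / band_s[1]) / (fs / 2))
  min_sep <- ceiling(band_s[1] / cfg$grid_step_s)
  raw_all <- numeric(0); filt_all <- numeric(0)
  segments <- list()
  for (g in unique(seg_id)) {
    seg <- s[seg_id == g, , drop = FALSE]
    if (nrow(seg) < 2L || max(seg$t_s) - min(seg$t_s) < 2 * band_s[1]) next
    grid <- seq(min(seg$t_s), max(seg$t_s), by = cfg$grid_step_s)
    y <- approx(seg$t_s, seg$resp_rate_bpm, xout = grid)$y - night_median
    yf <- filtfilt(filt$b, filt$a, y)
    raw_all <- c(raw_all, y); filt_all <- c(filt_all, yf)
    segments[[length(segments) + 1L]] <- list(grid = grid, yf = yf)
  }
  if (!length(segments)) return(result(NA_real_, numeric(0), "too_short"))
  if (sd(filt_all) < cfg$band_power_ratio_min * sd(raw_all))
    return(result(NA_real_, numeric(0), "low_band_power"))
  prom <- cfg$peak_prominence_sd * sd(filt_all)
  peak_times <- numeric(0); intervals <- numeric(0)
  for (seg in segments) {
    pk <- find_peaks(seg$yf, min_separation = min_sep, min_prominence = prom)
    pt <- seg$grid[pk]
    peak_times <- c(peak_times, pt)
    if (length(pt) > 1L) intervals <- c(intervals, diff(pt))
  }
  if (length(peak_times) < 3L || length(intervals) < 2L)
    return(result(NA_real_, peak_times, "too_few_peaks"))
  period <- mean(intervals) / 60
  if (period < cfg$ultradian_period_band_min[1] || period > cfg$ultradian_period_band_min[2])
    return(result(NA_real_, peak_times, "period_out_of_band"))
  result(period, peak_times, "ok")
}

#' @export
print.ultradian_result <- function(x, ...) {
  if (is.na(x$period_min)) {
    cat(sprintf("<ultradian_result> period undefined (%s), %d peak(s)\n", x$reason, x$n_peaks))
  } else {
    cat(sprintf("<ultradian_result> period %.1f min from %d peaks\n", x$period_min, x$n_peaks))
  }
  invisible(x)
}

#' Spectral cross-check of the ultradian period
#'
#' Diagnostic companion to [ultradian_cycle()]: the periodogram argmax of the
#' median-removed, gridded quality-passing series inside the search band.
#' Not used by the main pipeline (which is peak-based by design).
#'
#' @param night a [respiration_night()].
#' @param cfg an [analysis_config()].
#' @return Period in minutes at the in-band periodogram maximum, or `NA`.
#' @export
ultradian_spectral_check <- function(night, cfg = NULL) {
  cfg <- as_config(cfg)
  s <- night$samples[quality_mask(night, cfg), , drop = FALSE]
  if (nrow(s) < 8L) return(NA_real_)
  grid <- seq(min(s$t_s), max(s$t_s), by = cfg$grid_step_s)
  y <- approx(s$t_s, s$resp_rate_bpm, xout = grid)$y
  y <- y - median(y)
  sp <- stats::spec.pgram(stats::ts(y, deltat = cfg$grid_step_s), plot = FALSE,
                          detrend = TRUE, taper = 0.1)
  period_min <- (1 / sp$freq) / 60
  in_band <- period_min >= cfg$ultradian_period_band_min[1] &
    period_min <= cfg$ultradian_period_band_min[2]
  if (!any(in_band)) return(NA_real_)
  period_min[in_band][which.max(sp$spec[in_band])]
}
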