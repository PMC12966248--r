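#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with the study defaults.
#' All windowed quality metrics use the same 10-min window; thresholds are the
#' ones applied to the real recordings (13 mg persistent-movement threshold on
#' the SD of the acceleration vector magnitude, 150 non-physiological intervals
#' per 10-min window, 25-interval 1-min heart-rate gate, 50/100-interval
#' coverage gates, 0.35 respiration autocorrelation threshold, 30--120 min
#' ultradian search band).
#'
#' @param movement_sd_threshold_mg persistent-movement threshold on the
#'   windowed SD of the acceleration vector magnitude, in milli-g.
#' @param window_s quality/wear analysis window length in seconds (10 min).
#' @param nonphysio_limit_per_window flag a window when more than this many
#'   R-R intervals fall outside the physiological range.
#' @param rr_physio_lower_ms,rr_physio_upper_ms physiological R-R range in ms.
#'   Defaults 250--1000 ms (240 down to 60 bpm, appropriate for this age
#'   group).  The range is a configuration value, not a measured constant:
#'   change it for other populations.
#' @param min_intervals_hr_coverage minimum physiological intervals per window
#'   for the window to count as heart-rate coverage.
#' @param min_intervals_hrv_window minimum physiological intervals per 10-min
#'   window for an SDRRI value to be emitted.
#' @param min_intervals_hr_minute minimum physiological intervals per 1-min
#'   segment for a heart-rate value to be emitted.
#' @param min_beats_worn minimum physiological intervals in a window for a
#'   "detectable heartbeat" (device worn and attached).  The weakest faithful
#'   reading of the wear rule is 1.
#' @param autocorr_threshold respiration samples pass quality iff their
#'   autocorrelation is strictly greater than this.
#' @param ultradian_period_band_min length-2 numeric, ultradian period search
#'   band in minutes.
#' @param hrv_subsegment_s length of the SDRRI sub-segments (2 min).
#' @param min_subsegment_intervals minimum intervals for a sub-segment SD.
#' @param filter_order Butterworth band-pass order used (before the band-pass
#'   transformation doubles it) in the ultradian pipeline.
#' @param peak_prominence_sd peak acceptance: prominence must be at least this
#'   multiple of the band-passed signal SD.
#' @param band_power_ratio_min noise guard: the ultradian period is undefined
#'   unless sd(band-passed)/sd(median-removed input) reaches this ratio.
#' @param gap_bridge_s interpolate across quality gaps up to this length;
#'   split the night at longer gaps.
#' @param grid_step_s uniform resampling step of the ultradian pipeline.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$movement_sd_threshold_mg
#' @export
analysis_config <- function(movement_sd_threshold_mg = 13,
                            window_s = 600,
                            nonphysio_limit_per_window = 150,
                            rr_physio_lower_ms = 250,
                            rr_physio_upper_ms = 1000,
                            min_intervals_hr_coverage = 50,
                            min_intervals_hrv_window = 100,
                            min_intervals_hr_minute = 25,
                            min_beats_worn = 1,
                            autocorr_threshold = 0.35,
                            ultradian_period_band_min = c(30, 120),
                            hrv_subsegment_s = 120,
                            min_subsegment_intervals = 2,
                            filter_order = 2,
                            peak_prominence_sd = 0.5,
                            band_power_ratio_min = 0.4,
                            gap_bridge_s = 600,
                            grid_step_s = 60) {
  cfg <- list(
    movement_sd_threshold_mg = movement_sd_threshold_mg,
    window_s = window_s,
    nonphysio_limit_per_window = nonphysio_limit_per_window,
    rr_physio_lower_ms = rr_physio_lower_ms,
    rr_physio_upper_ms = rr_physio_upper_ms,
    min_intervals_hr_coverage = min_intervals_hr_coverage,
    min_intervals_hrv_window = min_intervals_hrv_window,
    min_intervals_hr_minute = min_intervals_hr_minute,
    min_beats_worn = min_beats_worn,
    autocorr_threshold = autocorr_threshold,
    ultradian_period_band_min = as.numeric(ultradian_period_band_min),
    hrv_subsegment_s = hrv_subsegment_s,
    min_subsegment_intervals = min_subsegment_intervals,
    filter_order = filter_order,
    peak_prominence_sd = peak_prominence_sd,
    band_power_ratio_min = band_power_ratio_min,
    gap_bridge_s = gap_bridge_s,
    grid_step_s = grid_step_s
  )
  scalars <- setdiff(names(cfg), c("ultradian_period_band_min", "autocorr_threshold",
                                   "peak_prominence_sd", "band_power_ratio_min"))
  for (nm in scalars) {
    if (!is_scalar_num(cfg[[nm]]) || cfg[[nm]] <= 0)
      config_error("analysis_config: `", nm, "` must be a positive scalar")
  }
  if (!is_scalar_num(cfg$autocorr_threshold))
    config_error("analysis_config: `autocorr_threshold` must be a scalar")
  if (cfg$rr_physio_lower_ms >= cfg$rr_physio_upper_ms)
    config_error("analysis_config: physiological range lower bound must be < upper bound")
  band <- cfg$ultradian_period_band_min
  if (length(band) != 2L || any(!is.finite(band)) || band[1] <= 0 || band[1] >= band[2])
    config_error("analysis_config: `ultradian_period_band_min` must be (lower, upper), 0 < lower < upper")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# Coerce/validate a cfg argument; NULL means defaults.
as_config <- function(cfg) {
  if (is.null(cfg)) return(analysis_config())
  if (!inherits(cfg, "analysis_config"))
    config_error("`cfg` must be created by analysis_config()")
  cfg
}
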