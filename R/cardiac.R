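# Validity-gated heart rate and SDRRI heart-rate variability from an R-R
# stream.  Segment membership rule: an interval belongs to the segment that
# contains its beat's end time.  Sample SD (n - 1) throughout.

#' Filter an R-R stream to the physiological range
#'
#' Keeps intervals inside `[rr_physio_lower_ms, rr_physio_upper_ms]` and
#' counts the excluded intervals per 10-min window.
#'
#' @param rr an [rr_series()].
#' @param cfg an [analysis_config()].
#' @return A list with `series` (the filtered [rr_series()], continuity not
#'   enforced) and `outside_counts` (data frame `window_start_s`,
#'   `n_outside`).
#' @examples
#' rr <- rr_series(t_s = c(0.5, 1.0, 3.0), rr_ms = c(500, 500, 2000),
#'                 check_continuity = FALSE)
#' filter_physiological(rr)$outside_counts
#' @export
filter_physiological <- function(rr, cfg = NULL) {
  cfg <- as_config(cfg)
  stopifnot(inherits(rr, "rr_series"))
  b <- rr$beats
  inside <- b$rr_ms >= cfg$rr_physio_lower_ms & b$rr_ms <= cfg$rr_physio_upper_ms
  span <- if (nrow(b)) max(b$t_s) else 0
  nw <- if (span > 0) n_windows(span, cfg$window_s) else 0L
  counts <- data.frame(
    window_start_s = (seq_len(nw) - 1L) * cfg$window_s,
    n_outside = tabulate(window_index(b$t_s[!inside], cfg$window_s) + 1L, nbins = nw)
  )
  list(series = rr_series(t_s = b$t_s[inside], rr_ms = b$rr_ms[inside],
                          start_time = rr$start_time, check_continuity = FALSE),
       outside_counts = counts)
}

#' Minute-by-minute heart rate
#'
#' For every 1-min segment containing at least `cfg$min_intervals_hr_minute`
#' (default 25) physiological R-R intervals, the heart rate is
#' `60000 / mean(rr_ms)`; other minutes are undefined (`NA`).
#'
#' @param rr an [rr_series()]; non-physiological intervals are removed
#'   internally.
#' @param cfg an [analysis_config()].
#' @return An `hr_series`: data frame with `minute_start_s`, `hr_bpm`
#'   (`NA` where gated out) and `n_intervals`.
#' @export
heart_rate_series <- function(rr, cfg = NULL) {
  cfg <- as_config(cfg)
  b <- filter_physiological(rr, cfg)$series$beats
  span <- if (nrow(rr$beats)) max(rr$beats$t_s) else 0
  nmin <- if (span > 0) max(1L, ceiling(span / 60)) else 0L
  idx <- window_index(b$t_s, 60) + 1L
  n_int <- tabulate(idx, nbins = nmin)
  sums <- numeric(nmin)
  if (nrow(b)) {
    agg <- tapply(b$rr_ms, idx, sum)
    sums[as.integer(names(agg))] <- agg
  }
  hr <- ifelse(n_int >= cfg$min_intervals_hr_minute, 60000 / (sums / pmax(n_int, 1L)), NA_real_)
  structure(data.frame(minute_start_s = (seq_len(nmin) - 1L) * 60,
                       hr_bpm = hr, n_intervals = n_int),
            class = c("hr_series", "data.frame"))
}

#' Windowed SDRRI heart-rate variability
#'
#' For every 10-min window containing at least `cfg$min_intervals_hrv_window`
#' (default 100) physiological intervals, the SDRRI is computed as the sample
#' SD of the intervals within each 2-min sub-segment, averaged over the
#' sub-segments with at least `cfg$min_subsegment_intervals` intervals (the
#' SDNN-index convention).  Windows failing the gate are undefined (`NA`).
#'
#' @param rr an [rr_series()]; filtered internally.
#' @param cfg an [analysis_config()].
#' @return An `hrv_series`: data frame with `window_start_s`, `sdrri_ms`
#'   (`NA` where gated out) and `n_intervals`; per-sub-segment SDs are kept
#'   in `attr(, "subsegments")`.
#' @export
hrv_series <- function(rr, cfg = NULL) {
  cfg <- as_config(cfg)
  b <- filter_physiological(rr, cfg)$series$beats
  span <- if (nrow(rr$beats)) max(rr$beats$t_s) else 0
  nw <- if (span > 0) n_windows(span, cfg$window_s) else 0L
  starts <- (seq_len(nw) - 1L) * cfg$window_s
  widx <- window_index(b$t_s, cfg$window_s) + 1L
  n_int <- tabulate(widx, nbins = nw)
  sub_per_win <- max(1L, floor(cfg$window_s / cfg$hrv_subsegment_s))
  sdrri <- rep(NA_real_, nw)
  subs <- vector("list", nw)
  for (i in seq_len(nw)) {
    subs[[i]] <- rep(NA_real_, sub_per_win)
    if (n_int[i] < cfg$min_intervals_hrv_window) next
    sel <- widx == i
    sub_idx <- window_index(b$t_s[sel] - starts[i], cfg$hrv_subsegment_s) + 1L
    sub_idx <- pmin(sub_idx, sub_per_win)  # boundary beat at window end
    for (j in seq_len(sub_per_win)) {
      v <- b$rr_ms[sel][sub_idx == j]
      if (length(v) >= cfg$min_subsegment_intervals) subs[[i]][j] <- sd(v)
    }
    if (any(!is.na(subs[[i]]))) sdrri[i] <- mean(subs[[i]], na.rm = TRUE)
  }
  structure(data.frame(window_start_s = starts, sdrri_ms = sdrri, n_intervals = n_int),
            subsegments = subs,
            class = c("hrv_series", "data.frame"))
}

#' Signal-quality coverage report
#'
#' Coverage proportions of 10-min windows with at least 50 (heart rate) or
#' 100 (HRV) physiological intervals, and the windows whose count of
#' non-physiological intervals exceeds 150 (flagged).  When a
#' `wear_state_series` is supplied, proportions are computed over the
#' worn-attached windows only.
#'
#' @param rr an [rr_series()].
#' @param cfg an [analysis_config()].
#' @param states optional `wear_state_series` from [classify_wear()].
#' @return An object of class `quality_report`: `prop_hr_coverage`,
#'   `prop_hrv_coverage` (NA when there are no eligible windows),
#'   `flagged_windows` (start times, seconds), `n_windows`.
#' @export
quality_report <- function(rr, cfg = NULL, states = NULL) {
  cfg <- as_config(cfg)
  fp <- filter_physiological(rr, cfg)
  b <- fp$series$beats
  nw <- nrow(fp$outside_counts)
  physio_counts <- tabulate(window_index(b$t_s, cfg$window_s) + 1L, nbins = nw)
  eligible <- rep(TRUE, nw)
  if (!is.null(states)) {
    stopifnot(inherits(states, "wear_state_series"))
    m <- match(fp$outside_counts$window_start_s, states$window_start_s)
    eligible <- !is.na(m) & states$state[pmax(m, 1L)] == "worn_attached"
  }
  n_elig <- sum(eligible)
  flagged <- fp$outside_counts$window_start_s[
    fp$outside_counts$n_outside > cfg$nonphysio_limit_per_window]
  structure(list(
    prop_hr_coverage = if (n_elig) mean(physio_counts[eligible] >= cfg$min_intervals_hr_coverage) else NA_real_,
    prop_hrv_coverage = if (n_elig) mean(physio_counts[eligible] >= cfg$min_intervals_hrv_window) else NA_real_,
    flagged_windows = flagged,
    n_windows = n_elig
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d window(s); HR coverage %s; HRV coverage %s; %d flagged\n",
              x$n_windows,
              if (is.na(x$prop_hr_coverage)) "NA" else sprintf("%.2f", x$prop_hr_coverage),
              if (is.na(x$prop_hrv_coverage)) "NA" else sprintf("%.2f", x$prop_hrv_coverage),
              length(x$flagged_windows)))
  invisible(x)
}

#' Z-score a series against a child's own baseline
#'
#' Expresses each defined value as the number of standard deviations from the
#' mean of the child's defined values (the baseline).  Undefined (gated-out)
#' points stay undefined.
#'
#' @param x numeric vector, or an `hr_series` / `hrv_series` (the value
#'   column is z-scored and returned as `hr_z` / `sdrri_z`).
#' @param baseline numeric vector of baseline values; defaults to the defined
#'   values of `x` itself (per-child, whole-recording baseline).
#' @param child_id optional label used in error messages.
#' @return Same shape as `x` with values replaced by z-scores.
#' @export
zscore <- function(x, baseline = NULL, child_id = NULL) UseMethod("zscore")

#' @export
zscore.default <- function(x, baseline = NULL, child_id = NULL) {
  if (is.null(baseline)) baseline <- x[!is.na(x)]
  baseline <- baseline[!is.na(baseline)]
  if (length(baseline) < 2L)
    validation_error("zscore: baseline needs >= 2 defined values",
                     if (!is.null(child_id)) paste0(" (child ", child_id, ")") else "")
  s <- sd(baseline)
  if (s == 0)
    validation_error("zscore: zero-variance baseline",
                     if (!is.null(child_id)) paste0(" for child ", child_id) else "")
  (x - mean(baseline)) / s
}

#' @export
zscore.hr_series <- function(x, baseline = NULL, child_id = NULL) {
  x$hr_z <- zscore(x$hr_bpm, baseline, child_id)
  x
}

#' @export
zscore.hrv_series <- function(x, baseline = NULL, child_id = NULL) {
  x$sdrri_z <- zscore(x$sdrri_ms, baseline, child_id)
  x
}
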