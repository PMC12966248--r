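# Integration of diary events with physiological series, and the nap-response
# analysis (z-scored HR/HRV around parent-labelled naps).

#' Build an integrated diary/physiology timeline
#'
#' Merges the minute-level heart rate, per-minute movement (SD of the
#' acceleration vector magnitude), the wear-state classification and the
#' parent diary into one time-indexed bundle.  Every diary event is annotated
#' with its mean heart rate and mean activity over the defined minutes it
#' overlaps; events extending beyond the recording span are clipped with a
#' note.
#'
#' @param hr an `hr_series` from [heart_rate_series()].
#' @param wear a `wear_state_series` from [classify_wear()].
#' @param accel an [accel_series()].
#' @param diary a [diary_log()] or `NULL`.
#' @param anchor ISO-8601 wall-clock time of `t = 0` for all series.
#' @param child_id optional label.
#' @return An object of class `timeline_bundle`: `minutes` (data frame
#'   `minute_start_s`, `hr_bpm`, `activity_sd_mg`, `wear_state`), `events`
#'   (diary entries with `start_s`, `end_s`, `mean_hr_bpm`,
#'   `mean_activity_sd_mg`, `clipped`), `anchor`, `child_id`.
#' @export
build_timeline <- function(hr, wear, accel, diary = NULL,
                           anchor = "1970-01-01T00:00:00Z", child_id = NULL) {
  stopifnot(inherits(hr, "hr_series"), inherits(wear, "wear_state_series"),
            inherits(accel, "accel_series"))
  if (nrow(hr) == 0L) validation_error("build_timeline: empty heart-rate series")
  accel_span <- nrow(accel$samples) / accel$sample_rate_hz
  hr_span <- max(hr$minute_start_s) + 60
  if (accel_span <= min(hr$minute_start_s) || hr_span <= 0)
    validation_error("build_timeline: accelerometry does not overlap the heart-rate series")
  span <- max(hr_span, accel_span)
  minutes <- data.frame(minute_start_s = seq(0, span - 1, by = 60))
  minutes$hr_bpm <- hr$hr_bpm[match(minutes$minute_start_s, hr$minute_start_s)]
  minutes$activity_sd_mg <- vapply(minutes$minute_start_s, function(t0)
    vector_magnitude_sd(accel, c(t0, t0 + 60)), 0)
  widx <- match(floor(minutes$minute_start_s / attr(wear, "window_s")) * attr(wear, "window_s"),
                wear$window_start_s)
  minutes$wear_state <- wear$state[widx]
  events <- NULL
  if (!is.null(diary) && nrow(diary)) {
    t0 <- parse_iso8601(anchor)
    ev <- as.data.frame(diary)
    ev$start_s <- as.numeric(difftime(parse_iso8601(ev$start), t0, units = "secs"))
    ev$end_s <- as.numeric(difftime(parse_iso8601(ev$end), t0, units = "secs"))
    ev$clipped <- ev$start_s < 0 | ev$end_s > span
    if (any(ev$clipped))
      message(sprintf("build_timeline: %d diary event(s) clipped to the recording span",
                      sum(ev$clipped)))
    ev$start_s <- pmax(ev$start_s, 0)
    ev$end_s <- pmin(ev$end_s, span)
    ev$mean_hr_bpm <- NA_real_
    ev$mean_activity_sd_mg <- NA_real_
    for (i in seq_len(nrow(ev))) {
      if (ev$end_s[i] <= ev$start_s[i]) next
      sel <- minutes$minute_start_s >= ev$start_s[i] & minutes$minute_start_s < ev$end_s[i]
      if (any(sel & !is.na(minutes$hr_bpm)))
        ev$mean_hr_bpm[i] <- mean(minutes$hr_bpm[sel], na.rm = TRUE)
      if (any(sel & !is.na(minutes$activity_sd_mg)))
        ev$mean_activity_sd_mg[i] <- mean(minutes$activity_sd_mg[sel], na.rm = TRUE)
    }
    events <- ev
  }
  structure(list(child_id = child_id, minutes = minutes, events = events,
                 anchor = anchor),
            class = "timeline_bundle")
}

#' @export
print.timeline_bundle <- function(x, ...) {
  cat(sprintf("<timeline_bundle>%s %d minutes, %d diary event(s), anchor %s\n",
              if (is.null(x$child_id)) "" else paste0(" ", x$child_id),
              nrow(x$minutes), if (is.null(x$events)) 0L else nrow(x$events),
              x$anchor))
  invisible(x)
}

#' Plot a timeline bundle
#'
#' Three stacked base-graphics panels: minute heart rate, minute activity,
#' and diary events as labelled spans.
#'
#' @param x a `timeline_bundle`.
#' @param ... unused.
#' @export
plot.timeline_bundle <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  th <- x$minutes$minute_start_s / 3600
  plot(th, x$minutes$hr_bpm, type = "l", xlab = "", ylab = "HR (bpm)")
  plot(th, x$minutes$activity_sd_mg, type = "l", xlab = "", ylab = "Activity (mg SD)")
  plot(range(th), c(0, 1), type = "n", xlab = "hours", ylab = "events", yaxt = "n")
  if (!is.null(x$events) && nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      graphics::rect(x$events$start_s[i] / 3600, 0.2, x$events$end_s[i] / 3600, 0.8,
                     col = "grey85", border = "grey40")
      graphics::text((x$events$start_s[i] + x$events$end_s[i]) / 7200, 0.5,
                     x$events$label[i], cex = 0.7)
    }
  }
  invisible(x)
}

#' Export a timeline as tidy long-format data
#'
#' @param bundle a `timeline_bundle`.
#' @return Data frame with columns `t_s`, `variable`, `value`.
#' @export
timeline_long <- function(bundle) {
  stopifnot(inherits(bundle, "timeline_bundle"))
  m <- bundle$minutes
  rbind(
    data.frame(t_s = m$minute_start_s, variable = "hr_bpm", value = m$hr_bpm),
    data.frame(t_s = m$minute_start_s, variable = "activity_sd_mg", value = m$activity_sd_mg),
    data.frame(t_s = m$minute_start_s, variable = "wear_state",
               value = as.numeric(factor(m$wear_state, levels = WEAR_STATES)))
  )
}

#' Physiological response to a labelled nap
#'
#' Z-scores the heart-rate and HRV series against the child's own baseline
#' (all defined values, whole recording by default), restricts them to the
#' nap window plus configurable flanks, and reports the extrema inside the
#' nap window itself.
#'
#' @param hr an `hr_series`.
#' @param hrv an `hrv_series`.
#' @param nap_window numeric `c(start_s, end_s)`.
#' @param flank_s context carried either side of the nap (default 30 min).
#' @param hr_baseline,hrv_baseline optional explicit baseline values
#'   (defaults: all defined values of each series).
#' @param child_id optional label for error messages.
#' @return An object of class `nap_response`: `nap_window`, `hr_z` and
#'   `hrv_z` (data frames over the flanked window), `min_hr_z`, `max_hrv_z`
#'   (`NA` with a `reason` when no defined points fall inside the nap).
#' @export
nap_response <- function(hr, hrv, nap_window, flank_s = 1800,
                         hr_baseline = NULL, hrv_baseline = NULL,
                         child_id = NULL) {
  stopifnot(inherits(hr, "hr_series"), inherits(hrv, "hrv_series"),
            length(nap_window) == 2L, nap_window[1] < nap_window[2])
  span <- max(hr$minute_start_s) + 60
  if (nap_window[1] >= span || nap_window[2] <= 0)
    validation_error("nap_response: nap window lies outside the recording")
  hr_z <- zscore(hr, baseline = hr_baseline, child_id = child_id)
  hrv_z <- zscore(hrv, baseline = hrv_baseline, child_id = child_id)
  lo <- nap_window[1] - flank_s; hi <- nap_window[2] + flank_s
  hr_z <- hr_z[hr_z$minute_start_s >= lo & hr_z$minute_start_s < hi, , drop = FALSE]
  hrv_z <- hrv_z[hrv_z$window_start_s >= lo & hrv_z$window_start_s < hi, , drop = FALSE]
  in_nap_hr <- hr_z$minute_start_s >= nap_window[1] & hr_z$minute_start_s < nap_window[2]
  in_nap_hrv <- hrv_z$window_start_s >= nap_window[1] & hrv_z$window_start_s < nap_window[2]
  hr_vals <- hr_z$hr_z[in_nap_hr]
  hrv_vals <- hrv_z$sdrri_z[in_nap_hrv]
  reason <- "ok"
  min_hr <- if (any(!is.na(hr_vals))) min(hr_vals, na.rm = TRUE) else NA_real_
  max_hrv <- if (any(!is.na(hrv_vals))) max(hrv_vals, na.rm = TRUE) else NA_real_
  if (is.na(min_hr) && is.na(max_hrv)) reason <- "no_defined_points_in_window"
  structure(list(nap_window = nap_window, hr_z = hr_z, hrv_z = hrv_z,
                 min_hr_z = min_hr, max_hrv_z = max_hrv, reason = reason),
            class = "nap_response")
}

#' @export
print.nap_response <- function(x, ...) {
  cat(sprintf("<nap_response> nap [%.0f, %.0f) s: min HR z = %s, max HRV z = %s%s\n",
              x$nap_window[1], x$nap_window[2],
              if (is.na(x$min_hr_z)) "NA" else sprintf("%.2f", x$min_hr_z),
              if (is.na(x$max_hrv_z)) "NA" else sprintf("%.2f", x$max_hrv_z),
              if (x$reason != "ok") paste0(" (", x$reason, ")") else ""))
  invisible(x)
}
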