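#' R-R interval series
#'
#' A timestamped stream of R-R intervals from one wear period of the
#' heart-rate monitor.  Beat `k` occurs at `t_s[k]` seconds after
#' `start_time`, and `rr_ms[k]` is the interval that *ends* at that beat, so
#' `t_s = cumsum(rr_ms) / 1000` for a gap-free stream.
#'
#' @param t_s numeric, beat times in seconds since `start_time`, strictly
#'   increasing.
#' @param rr_ms numeric, interval durations in milliseconds, all positive.
#' @param start_time ISO-8601 wall-clock anchor of `t_s = 0`.
#' @param check_continuity if `TRUE` (the default for device streams), verify
#'   that successive beat-time differences equal the later interval within
#'   1 ms.  Set `FALSE` for derived streams (e.g. after physiological
#'   filtering) where beats have been removed.
#' @return An object of class `rr_series` with fields `start_time` and
#'   `beats` (a data frame with columns `t_s`, `rr_ms`).
#' @examples
#' rr <- rr_series(t_s = cumsum(rep(0.5, 10)), rr_ms = rep(500, 10))
#' rr
#' @export
rr_series <- function(t_s = numeric(), rr_ms = numeric(),
                      start_time = "1970-01-01T00:00:00Z",
                      check_continuity = TRUE) {
  t_s <- as.numeric(t_s); rr_ms <- as.numeric(rr_ms)
  if (length(t_s) != length(rr_ms))
    validation_error("rr_series: t_s and rr_ms must have equal length")
  if (length(rr_ms) && any(!is.finite(rr_ms) | rr_ms <= 0)) {
    bad <- which(!is.finite(rr_ms) | rr_ms <= 0)[1]
    validation_error("rr_series: rr_ms must be positive and finite (first offence at beat ", bad, ")")
  }
  if (length(t_s) > 1L && any(diff(t_s) <= 0)) {
    bad <- which(diff(t_s) <= 0)[1] + 1L
    validation_error("rr_series: t_s must be strictly increasing (first offence at beat ", bad, ")")
  }
  if (check_continuity && length(t_s) > 1L) {
    gap_ms <- diff(t_s) * 1000 - rr_ms[-1]
    if (any(abs(gap_ms) > 1)) {
      bad <- which(abs(gap_ms) > 1)[1] + 1L
      validation_error("rr_series: beat-time difference disagrees with rr_ms by >1 ms at beat ", bad)
    }
  }
  structure(list(start_time = as.character(start_time),
                 beats = data.frame(t_s = t_s, rr_ms = rr_ms)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- nrow(x$beats)
  cat(sprintf("<rr_series> %d beats, start %s", n, x$start_time))
  if (n) cat(sprintf(", span %.1f s, median RR %.0f ms",
                     diff(range(x$beats$t_s)), median(x$beats$rr_ms)))
  cat("\n")
  invisible(x)
}

#' Tri-axial accelerometry series
#'
#' @param ax_mg,ay_mg,az_mg numeric axis samples in milli-g (1 mg = g/1000).
#' @param sample_rate_hz sampling rate in Hz (default 25, the generator's
#'   cadence).
#' @param start_time ISO-8601 anchor shared with the R-R stream.
#' @return An object of class `accel_series`.
#' @export
accel_series <- function(ax_mg = numeric(), ay_mg = numeric(), az_mg = numeric(),
                         sample_rate_hz = 25,
                         start_time = "1970-01-01T00:00:00Z") {
  if (!is_scalar_num(sample_rate_hz) || sample_rate_hz <= 0)
    validation_error("accel_series: sample_rate_hz must be a positive scalar")
  n <- length(ax_mg)
  if (length(ay_mg) != n || length(az_mg) != n)
    validation_error("accel_series: axis vectors must have equal length")
  smp <- data.frame(ax_mg = as.numeric(ax_mg), ay_mg = as.numeric(ay_mg),
                    az_mg = as.numeric(az_mg))
  if (n && any(!is.finite(as.matrix(smp)))) {
    validation_error("accel_series: samples must be finite")
  }
  structure(list(start_time = as.character(start_time),
                 sample_rate_hz = sample_rate_hz, samples = smp),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples @ %g Hz (%.1f s), start %s\n",
              nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz, x$start_time))
  invisible(x)
}

# Sample times (s since anchor) of an accel series.
accel_times <- function(accel) {
  n <- nrow(accel$samples)
  if (n == 0L) return(numeric())
  (seq_len(n) - 1L) / accel$sample_rate_hz
}

#' One night of respiration-monitor output
#'
#' A nightly log from the nappy-cover sleep monitor: a respiration-rate series
#' (breaths/min), the device's per-sample autocorrelation quality score in
#' `[-1, 1]`, and a sleeping-position category.
#'
#' @param t_s sample times, seconds since `start_time`, strictly increasing.
#' @param resp_rate_bpm respiration rate, breaths per minute, non-negative.
#' @param autocorr per-sample autocorrelation quality in `[-1, 1]`.
#' @param position character, one of
#'   `r paste0('"', paste(POSITION_LEVELS, collapse = '", "'), '"')`.
#'   Unrecognised labels are mapped to `"unknown"` with a warning.
#' @param start_time ISO-8601 anchor.
#' @return An object of class `respiration_night`.
#' @export
respiration_night <- function(t_s = numeric(), resp_rate_bpm = numeric(),
                              autocorr = numeric(), position = character(),
                              start_time = "1970-01-01T00:00:00Z") {
  n <- length(t_s)
  if (length(resp_rate_bpm) != n || length(autocorr) != n || length(position) != n)
    validation_error("respiration_night: all sample vectors must have equal length")
  t_s <- as.numeric(t_s)
  if (n > 1L && any(diff(t_s) <= 0)) {
    bad <- which(diff(t_s) <= 0)[1] + 1L
    validation_error("respiration_night: t_s must be strictly increasing (first offence at sample ", bad, ")")
  }
  if (n && any(!is.finite(resp_rate_bpm) | resp_rate_bpm < 0)) {
    bad <- which(!is.finite(resp_rate_bpm) | resp_rate_bpm < 0)[1]
    validation_error("respiration_night: resp_rate_bpm must be >= 0 (first offence at sample ", bad, ")")
  }
  if (n && any(!is.finite(autocorr) | autocorr < -1 | autocorr > 1)) {
    bad <- which(!is.finite(autocorr) | autocorr < -1 | autocorr > 1)[1]
    validation_error("respiration_night: autocorr must lie in [-1, 1] (first offence at sample ", bad, ")")
  }
  position <- as.character(position)
  unknown <- !(position %in% POSITION_LEVELS)
  if (any(unknown)) {
    warning(sprintf("respiration_night: %d unrecognised position label(s) (e.g. \"%s\") mapped to \"unknown\"",
                    sum(unknown), position[which(unknown)[1]]))
    position[unknown] <- "unknown"
  }
  structure(list(start_time = as.character(start_time),
                 samples = data.frame(t_s = t_s, resp_rate_bpm = as.numeric(resp_rate_bpm),
                                      autocorr = as.numeric(autocorr),
                                      position = position)),
            class = "respiration_night")
}

#' @export
print.respiration_night <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<respiration_night> %d samples, start %s", n, x$start_time))
  if (n) cat(sprintf(", span %.1f h", diff(range(x$samples$t_s)) / 3600))
  cat("\n")
  invisible(x)
}

#' Parent diary log
#'
#' @param start,end ISO-8601 timestamps; `start <= end` per entry.  Entries
#'   are sorted by `start`; overlaps are permitted.
#' @param label free-text description.
#' @param category one of
#'   `r paste0('"', paste(DIARY_CATEGORIES, collapse = '", "'), '"')`.
#'   Unrecognised categories are mapped to `"other"` with a warning.
#' @return An object of class `diary_log` (a data frame).
#' @export
diary_log <- function(start = character(), end = character(),
                      label = character(), category = character()) {
  n <- length(start)
  if (length(end) != n || length(label) != n || length(category) != n)
    validation_error("diary_log: all entry vectors must have equal length")
  st <- parse_iso8601(start); en <- parse_iso8601(end)
  if (n && any(en < st)) {
    bad <- which(en < st)[1]
    validation_error("diary_log: end precedes start at entry ", bad)
  }
  category <- as.character(category)
  unknown <- !(category %in% DIARY_CATEGORIES)
  if (any(unknown)) {
    warning(sprintf("diary_log: %d unrecognised categor(ies) mapped to \"other\"", sum(unknown)))
    category[unknown] <- "other"
  }
  d <- data.frame(start = as.character(start), end = as.character(end),
                  label = as.character(label), category = category)
  d <- d[order(st), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("diary_log", "data.frame"))
}

# Parse ISO-8601 timestamps to POSIXct (UTC).  Only storage-anchor arithmetic
# is supported; no time-zone logic beyond UTC.
parse_iso8601 <- function(x) {
  if (length(x) == 0L) return(as.POSIXct(character(), tz = "UTC"))
  x2 <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(x2, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out) & !is.na(x)))
    validation_error("could not parse ISO-8601 timestamp: ", x[which(is.na(out))[1]])
  out
}
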