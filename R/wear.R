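# Wear-state classification from joint ECG / accelerometry evidence.
#
# Per 10-min window: a detectable heartbeat (>= cfg$min_beats_worn
# physiological R-R intervals) implies worn and attached; otherwise persistent
# movement (SD of the acceleration vector magnitude > 13 mg) implies worn but
# not correctly attached; otherwise the device was not worn.

#' Windowed SD of the acceleration vector magnitude
#'
#' Sample SD (n - 1 denominator) of `sqrt(ax^2 + ay^2 + az^2)` over the
#' samples falling in the half-open window `[t0, t1)`.
#'
#' @param accel an [accel_series()].
#' @param window numeric `c(t0, t1)`, seconds since the series anchor.
#' @return SD in milli-g, or `NA_real_` for a window with fewer than two
#'   samples (undefined marker).
#' @examples
#' acc <- accel_series(ax_mg = rep(0, 100), ay_mg = rep(0, 100),
#'                     az_mg = rep(1000, 100), sample_rate_hz = 25)
#' vector_magnitude_sd(acc, c(0, 4))  # constant signal -> 0
#' @export
vector_magnitude_sd <- function(accel, window) {
  stopifnot(inherits(accel, "accel_series"), length(window) == 2L)
  t <- accel_times(accel)
  sel <- t >= window[1] & t < window[2]
  if (sum(sel) < 2L) return(NA_real_)
  vm <- sqrt(accel$samples$ax_mg[sel]^2 + accel$samples$ay_mg[sel]^2 +
               accel$samples$az_mg[sel]^2)
  sd(vm)
}

# Window index (0-based) of each beat/sample time; an interval belongs to the
# window containing its beat's *end* time.
window_index <- function(t, window_s) floor(t / window_s)

# Number of half-open windows covering [0, span_s).
n_windows <- function(span_s, window_s) max(1L, ceiling(span_s / window_s))

#' Classify wear state per window
#'
#' For every contiguous half-open window `[t, t + window_s)` covering the
#' recording: at least `cfg$min_beats_worn` R-R intervals inside the
#' physiological range means `worn_attached`; otherwise an SD of the
#' acceleration vector magnitude above `cfg$movement_sd_threshold_mg` means
#' `worn_detached`; otherwise `not_worn`.  A window with no heartbeat and no
#' accelerometry coverage is marked `not_worn` with a data-gap warning.
#'
#' @param rr an [rr_series()] (raw; filtered internally).
#' @param accel an [accel_series()] sharing the clock anchor.
#' @param cfg an [analysis_config()].
#' @return A `wear_state_series`: data frame with columns `window_start_s`
#'   and `state`, with the window length in `attr(, "window_s")`.
#' @export
classify_wear <- function(rr, accel, cfg = NULL) {
  cfg <- as_config(cfg)
  stopifnot(inherits(rr, "rr_series"), inherits(accel, "accel_series"))
  span <- max(if (nrow(rr$beats)) max(rr$beats$t_s) else 0,
              nrow(accel$samples) / accel$sample_rate_hz)
  if (span <= 0) validation_error("classify_wear: both streams are empty")
  nw <- n_windows(span, cfg$window_s)
  starts <- (seq_len(nw) - 1L) * cfg$window_s
  physio <- rr$beats$rr_ms >= cfg$rr_physio_lower_ms &
    rr$beats$rr_ms <= cfg$rr_physio_upper_ms
  beat_w <- window_index(rr$beats$t_s[physio], cfg$window_s)
  beat_counts <- tabulate(beat_w + 1L, nbins = nw)
  states <- character(nw)
  gap <- FALSE
  for (i in seq_len(nw)) {
    if (beat_counts[i] >= cfg$min_beats_worn) {
      states[i] <- "worn_attached"
    } else {
      sdvm <- vector_magnitude_sd(accel, c(starts[i], starts[i] + cfg$window_s))
      if (is.na(sdvm)) {
        gap <- TRUE
        states[i] <- "not_worn"
      } else if (sdvm > cfg$movement_sd_threshold_mg) {
        states[i] <- "worn_detached"
      } else {
        states[i] <- "not_worn"
      }
    }
  }
  if (gap)
    warning("classify_wear: window(s) without heartbeat or accelerometry coverage marked not_worn (data gap)")
  structure(data.frame(window_start_s = starts, state = states),
            window_s = cfg$window_s,
            class = c("wear_state_series", "data.frame"))
}

#' Roll up a wear-time summary
#'
#' Wear periods are maximal runs of windows not classified `not_worn`;
#' accidental detachments are `worn_attached -> worn_detached` transitions;
#' the error rate is the count of non-physiological R-R intervals recorded
#' during attached windows divided by attached minutes.
#'
#' @param states a `wear_state_series` from [classify_wear()].
#' @param rr the [rr_series()] the states were computed from.
#' @param cfg an [analysis_config()].
#' @return An object of class `wear_summary`: `n_wear_periods`,
#'   `total_wear_s`, `wear_attached_s`, `wear_detached_s`,
#'   `n_accidental_detachments`, `error_rate_per_min` (NA when no attached
#'   time).
#' @export
wear_summary <- function(states, rr, cfg = NULL) {
  cfg <- as_config(cfg)
  stopifnot(inherits(states, "wear_state_series"), inherits(rr, "rr_series"))
  window_s <- attr(states, "window_s")
  st <- states$state
  worn <- st != "not_worn"
  runs <- rle(worn)
  n_periods <- sum(runs$values)
  attached_s <- sum(st == "worn_attached") * window_s
  detached_s <- sum(st == "worn_detached") * window_s
  n_detach <- sum(st[-length(st)] == "worn_attached" & st[-1] == "worn_detached")
  nonphysio <- rr$beats$rr_ms < cfg$rr_physio_lower_ms |
    rr$beats$rr_ms > cfg$rr_physio_upper_ms
  beat_w <- window_index(rr$beats$t_s, window_s) + 1L
  idx <- pmin(pmax(beat_w, 1L), length(st))
  in_attached <- beat_w >= 1L & beat_w <= length(st) & st[idx] == "worn_attached"
  n_err <- sum(nonphysio & in_attached)
  err_rate <- if (attached_s > 0) n_err / (attached_s / 60) else NA_real_
  structure(list(n_wear_periods = n_periods,
                 total_wear_s = attached_s + detached_s,
                 wear_attached_s = attached_s,
                 wear_detached_s = detached_s,
                 n_accidental_detachments = n_detach,
                 error_rate_per_min = err_rate),
            class = "wear_summary")
}

#' @export
print.wear_summary <- function(x, ...) {
  cat(sprintf(paste0("<wear_summary> %d wear period(s); total %.1f h ",
                     "(attached %.1f h, detached %.1f h); %d accidental ",
                     "detachment(s); error rate %s/min\n"),
              x$n_wear_periods, x$total_wear_s / 3600, x$wear_attached_s / 3600,
              x$wear_detached_s / 3600, x$n_accidental_detachments,
              if (is.na(x$error_rate_per_min)) "NA" else sprintf("%.3f", x$error_rate_per_min)))
  invisible(x)
}
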