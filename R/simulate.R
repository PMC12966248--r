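#' Simulation profile for one heart-rate monitor recording
#'
#' Describes a synthetic wear period: a baseline heart rate with Gaussian
#' interval jitter, optional nap windows during which the heart rate dips
#' smoothly, optional detachment windows with no beats, a schedule of gross
#' movement states driving the accelerometer channel, and a fraction of beats
#' replaced by non-physiological artefact intervals.
#'
#' The nap dip depth is expressed in units of the baseline minute-to-minute
#' heart-rate standard deviation implied by the jitter (floored at 0.5 bpm),
#' so that z-score analyses of a `hr_dip_sd = 2` nap land near -2 regardless
#' of the absolute noise scale.  Ramps in and out of the dip last 5 min.
#'
#' @param duration_s recording length in seconds, > 0.
#' @param baseline_hr_bpm baseline heart rate, beats/min, > 0.
#' @param hr_jitter_ms SD of Gaussian noise added to each clean interval, ms.
#' @param artefact_fraction proportion in `[0, 1]` of beats replaced by
#'   intervals drawn uniformly from outside the physiological range
#'   (`(0, lower) U (upper, 3000)` ms).
#' @param nap_windows list of `c(start_s, end_s, hr_dip_sd)` triples.
#' @param detach_windows list of `c(start_s, end_s)` pairs with no beats.
#' @param movement_schedule list of `list(start_s, end_s, state)` with state
#'   in `"moving"`, `"still"`, `"off_body"`; must cover `[0, duration_s)`
#'   for [simulate_accel()].
#' @param seed integer seed; identical profiles give identical output.
#' @return An object of class `sim_profile`.
#' @examples
#' p <- sim_profile(duration_s = 60, baseline_hr_bpm = 120, hr_jitter_ms = 0)
#' simulate_rr_stream(p)
#' @export
sim_profile <- function(duration_s,
                        baseline_hr_bpm,
                        hr_jitter_ms = 15,
                        artefact_fraction = 0,
                        nap_windows = list(),
                        detach_windows = list(),
                        movement_schedule = list(list(0, duration_s, "still")),
                        seed = 1L) {
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    config_error("sim_profile: duration_s must be > 0")
  if (!is_scalar_num(baseline_hr_bpm) || baseline_hr_bpm <= 0)
    config_error("sim_profile: baseline_hr_bpm must be > 0")
  if (!is_scalar_num(hr_jitter_ms) || hr_jitter_ms < 0)
    config_error("sim_profile: hr_jitter_ms must be >= 0")
  if (!is_scalar_num(artefact_fraction) || artefact_fraction < 0 || artefact_fraction > 1)
    config_error("sim_profile: artefact_fraction must lie in [0, 1]")
  check_windows(nap_windows, duration_s, "sim_profile nap_windows")
  check_windows(detach_windows, duration_s, "sim_profile detach_windows")
  check_windows(movement_schedule, duration_s, "sim_profile movement_schedule")
  for (w in movement_schedule) {
    state <- as.character(w[[3]])
    if (!state %in% c("moving", "still", "off_body"))
      config_error("sim_profile: unknown movement state \"", state, "\"")
  }
  structure(list(duration_s = duration_s, baseline_hr_bpm = baseline_hr_bpm,
                 hr_jitter_ms = hr_jitter_ms, artefact_fraction = artefact_fraction,
                 nap_windows = nap_windows, detach_windows = detach_windows,
                 movement_schedule = movement_schedule, seed = as.integer(seed)),
            class = "sim_profile")
}

# Baseline minute-level HR SD implied by interval jitter (delta method on
# HR = 60000 / mean(rr) with ~baseline_hr beats per minute), floored at
# 0.5 bpm so dips stay visible for jitter-free profiles.
minute_hr_sd <- function(profile) {
  sd_mean_rr <- profile$hr_jitter_ms / sqrt(max(profile$baseline_hr_bpm, 1))
  max(profile$baseline_hr_bpm^2 / 60000 * sd_mean_rr, 0.5)
}

# Trapezoidal ramp: 0 outside [start, end], 1 in the plateau, linear 5-min
# ramps (shorter if the window is shorter).
nap_ramp <- function(t, start_s, end_s, ramp_s = 300) {
  ramp_s <- min(ramp_s, (end_s - start_s) / 2)
  up <- pmin(pmax((t - start_s) / ramp_s, 0), 1)
  down <- pmin(pmax((end_s - t) / ramp_s, 0), 1)
  pmin(up, down)
}

# Instantaneous target HR at times t (vectorised).
profile_hr_at <- function(profile, t) {
  hr <- rep(profile$baseline_hr_bpm, length(t))
  s <- minute_hr_sd(profile)
  for (w in profile$nap_windows) {
    dip <- as.numeric(w[[3]]) * s
    hr <- hr - dip * nap_ramp(t, as.numeric(w[[1]]), as.numeric(w[[2]]))
  }
  pmax(hr, 30)  # never let the target HR collapse
}

#' Simulate an R-R interval stream
#'
#' Emits beat times as cumulative sums of intervals.  Clean intervals are
#' `60000 / hr(t)` plus Gaussian jitter, where `hr(t)` follows the baseline
#' and nap dips of the profile.  A configured fraction of beats is replaced by
#' artefact intervals drawn uniformly from `(0, lower) U (upper, 3000)` ms so
#' they are unambiguously non-physiological.  Beats falling inside detachment
#' windows are removed; the first beat after a gap carries a single bridging
#' interval equal to the elapsed gap (as a Holter R-peak stream would), which
#' keeps the conservation identity `sum(rr_ms)/1000 == last - first beat time`
#' and is invisible to all physiologically gated metrics.
#'
#' @param profile a [sim_profile()].
#' @param cfg an [analysis_config()]; supplies the physiological range the
#'   artefact draw must avoid.
#' @return An [rr_series()].
#' @export
simulate_rr_stream <- function(profile, cfg = NULL) {
  if (!inherits(profile, "sim_profile")) config_error("profile must be a sim_profile")
  cfg <- as_config(cfg)
  lower <- cfg$rr_physio_lower_ms; upper <- cfg$rr_physio_upper_ms
  with_seed(profile$seed, {
    # Over-generate, then truncate at duration.  Two passes refine the
    # time-varying HR evaluation (dips are slow, so one refinement suffices).
    n_est <- ceiling(profile$duration_s * profile$baseline_hr_bpm / 60 * 1.5) + 20L
    noise <- rnorm(n_est, 0, profile$hr_jitter_ms)
    t_approx <- cumsum(rep(60 / profile$baseline_hr_bpm, n_est))
    for (pass in 1:2) {
      rr <- 60000 / profile_hr_at(profile, t_approx) + noise
      rr <- pmax(rr, 1)
      t_approx <- cumsum(rr) / 1000
    }
    # Artefact replacement.
    if (profile$artefact_fraction > 0) {
      idx <- which(runif(n_est) < profile$artefact_fraction)
      if (length(idx)) {
        rr[idx] <- draw_artefact(length(idx), lower, upper)
      }
    }
    t_s <- cumsum(rr) / 1000
    keep <- t_s <= profile$duration_s
    t_s <- t_s[keep]
    # Remove beats inside detachment windows; diffs of surviving beat times
    # become the emitted intervals (bridging interval spans each gap).
    for (w in profile$detach_windows) {
      t_s <- t_s[t_s < as.numeric(w[[1]]) | t_s >= as.numeric(w[[2]])]
    }
    if (length(t_s) == 0L) {
      rr_series()
    } else {
      rr_out <- c(t_s[1], diff(t_s)) * 1000
      rr_series(t_s = t_s, rr_ms = rr_out, check_continuity = FALSE)
    }
  })
}

# Uniform draw outside [lower, upper], inside (0, 3000) ms, weighted by the
# lengths of the two admissible segments.
draw_artefact <- function(n, lower, upper, cap_ms = 3000) {
  w_low <- lower / (lower + (cap_ms - upper))
  low <- runif(n) < w_low
  out <- numeric(n)
  out[low] <- runif(sum(low), 0, lower)
  out[!low] <- runif(sum(!low), upper, cap_ms)
  pmax(out, 1e-6)
}

#' Simulate tri-axial accelerometry for a movement schedule
#'
#' Produces milli-g samples with gravity (1000 mg) on the z axis and
#' state-dependent noise: `moving` windows get per-axis noise whose vector
#' magnitude SD clearly exceeds the 13 mg persistent-movement threshold,
#' `still` and `off_body` windows stay clearly below it.
#'
#' @param profile a [sim_profile()] whose `movement_schedule` covers
#'   `[0, duration_s)`.
#' @param sample_rate_hz sampling rate (default 25 Hz).
#' @param moving_sd_mg,still_sd_mg,off_sd_mg per-axis noise SDs by state.
#' @return An [accel_series()].
#' @export
simulate_accel <- function(profile, sample_rate_hz = 25,
                           moving_sd_mg = 50, still_sd_mg = 5, off_sd_mg = 1.5) {
  if (!inherits(profile, "sim_profile")) config_error("profile must be a sim_profile")
  sched <- profile$movement_schedule
  if (length(sched) == 0L) config_error("simulate_accel: empty movement_schedule")
  covered <- sum(vapply(sched, function(w) as.numeric(w[[2]]) - as.numeric(w[[1]]), 0))
  if (abs(covered - profile$duration_s) > 1e-6)
    config_error("simulate_accel: movement_schedule must cover [0, duration_s)")
  n <- floor(profile$duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  sd_by_state <- c(moving = moving_sd_mg, still = still_sd_mg, off_body = off_sd_mg)
  sds <- rep(NA_real_, n)
  for (w in sched) {
    state <- as.character(w[[3]])
    sel <- t >= as.numeric(w[[1]]) & t < as.numeric(w[[2]])
    sds[sel] <- sd_by_state[[state]]
  }
  sds[is.na(sds)] <- off_sd_mg
  with_seed(profile$seed + 1L, {
    accel_series(ax_mg = rnorm(n, 0, sds),
                 ay_mg = rnorm(n, 0, sds),
                 az_mg = 1000 + rnorm(n, 0, sds),
                 sample_rate_hz = sample_rate_hz)
  })
}

#' Respiration-night simulation profile
#'
#' @param duration_s night length in seconds.
#' @param base_rate_bpm baseline respiration rate, breaths/min.
#' @param ultradian_period_min period of the injected sleep-cycle
#'   oscillation, minutes; must lie in `[30, 120]`, or `0` to disable it.
#' @param ultradian_amplitude_bpm amplitude of the oscillation, breaths/min.
#' @param noise_sd_bpm Gaussian sample noise SD, breaths/min.
#' @param dropout_fraction proportion in `[0, 1]` of samples assigned an
#'   autocorrelation at or below the 0.35 quality threshold.
#' @param position_changes list of `list(time_s, position)`; position is
#'   piecewise constant, starting `"supine"` before the first change.
#' @param seed integer seed.
#' @return An object of class `resp_profile`.
#' @export
resp_profile <- function(duration_s,
                         base_rate_bpm = 25,
                         ultradian_period_min = 65,
                         ultradian_amplitude_bpm = 2,
                         noise_sd_bpm = 1,
                         dropout_fraction = 0,
                         position_changes = list(),
                         seed = 1L) {
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    config_error("resp_profile: duration_s must be > 0")
  if (!is_scalar_num(base_rate_bpm) || base_rate_bpm <= 0)
    config_error("resp_profile: base_rate_bpm must be > 0")
  if (!is_scalar_num(ultradian_period_min) ||
      (ultradian_period_min != 0 && (ultradian_period_min < 30 || ultradian_period_min > 120)))
    config_error("resp_profile: ultradian_period_min must lie in [30, 120], or 0 to disable")
  if (!is_scalar_num(dropout_fraction) || dropout_fraction < 0 || dropout_fraction > 1)
    config_error("resp_profile: dropout_fraction must lie in [0, 1]")
  if (!is_scalar_num(noise_sd_bpm) || noise_sd_bpm < 0)
    config_error("resp_profile: noise_sd_bpm must be >= 0")
  structure(list(duration_s = duration_s, base_rate_bpm = base_rate_bpm,
                 ultradian_period_min = ultradian_period_min,
                 ultradian_amplitude_bpm = ultradian_amplitude_bpm,
                 noise_sd_bpm = noise_sd_bpm, dropout_fraction = dropout_fraction,
                 position_changes = position_changes, seed = as.integer(seed)),
            class = "resp_profile")
}

#' Simulate one night of respiration-monitor output
#'
#' Rate series `base + amplitude * sin(2*pi*t/period) + noise` on a 30-s
#' cadence.  Samples selected for dropout receive an autocorrelation drawn
#' uniformly below the 0.35 quality threshold; all others draw above it.
#' Position is piecewise constant per `position_changes`.
#'
#' @param profile a [resp_profile()].
#' @param cadence_s sample spacing in seconds (default 30).
#' @param autocorr_threshold quality threshold separating dropout from good
#'   samples (default 0.35).
#' @return A [respiration_night()].
#' @export
simulate_respiration_night <- function(profile, cadence_s = 30,
                                       autocorr_threshold = 0.35) {
  if (!inherits(profile, "resp_profile")) config_error("profile must be a resp_profile")
  n <- floor(profile$duration_s / cadence_s)
  t <- seq(0, by = cadence_s, length.out = n)
  with_seed(profile$seed, {
    rate <- rep(profile$base_rate_bpm, n)
    if (profile$ultradian_period_min > 0) {
      rate <- rate + profile$ultradian_amplitude_bpm *
        sin(2 * pi * t / (profile$ultradian_period_min * 60))
    }
    rate <- pmax(rate + rnorm(n, 0, profile$noise_sd_bpm), 0)
    drop <- runif(n) < profile$dropout_fraction
    ac <- numeric(n)
    ac[drop] <- runif(sum(drop), 0, autocorr_threshold - 0.01)
    ac[!drop] <- runif(sum(!drop), autocorr_threshold + 0.01, 1)
    pos <- rep("supine", n)
    for (ch in profile$position_changes) {
      pos[t >= as.numeric(ch[[1]])] <- as.character(ch[[2]])
    }
    respiration_night(t_s = t, resp_rate_bpm = rate, autocorr = ac, position = pos)
  })
}

#' Simulate a study cohort with prescribed usable-unit counts
#'
#' Builds a cohort of child records whose usable-unit counts -- after the
#' default usability rules (>= 6 attached hours per usable monitor day,
#' >= 6 recorded hours per usable night) -- equal the requested counts, so
#' device-comparison logic can be exercised against known table inputs.
#' Usable days carry 8 attached hours and plausible daily HR/HRV means;
#' non-usable days carry 2 attached hours and no metrics.  Exactly
#' `nappa_nights` usable nights (9 h recordings) are emitted per child.
#'
#' @param n_children number of children.
#' @param per_child_success list (length `n_children`) of
#'   `c(nappa_nights, hr_days)` usable-unit counts; each count must be
#'   `<= study_days`.
#' @param seed integer seed.
#' @param study_days study window length (denominator for proportions).
#' @return An object of class `study_cohort`.
#' @examples
#' co <- simulate_cohort(1, list(c(7, 1)), seed = 1)
#' usable_units(co$children[[1]])
#' @export
simulate_cohort <- function(n_children, per_child_success, seed = 1L, study_days = 7) {
  if (!is_count(n_children)) config_error("simulate_cohort: n_children must be a count")
  if (n_children == 0L) {
    return(structure(list(children = list(), study_days = study_days),
                     class = "study_cohort"))
  }
  if (length(per_child_success) != n_children)
    config_error("simulate_cohort: per_child_success must have one entry per child")
  children <- vector("list", n_children)
  for (i in seq_len(n_children)) {
    pair <- as.numeric(per_child_success[[i]])
    if (length(pair) != 2L || !is_count(pair[1]) || !is_count(pair[2]))
      config_error("simulate_cohort: per_child_success entries must be (nappa_nights, hr_days) counts")
    if (any(pair > study_days))
      config_error("simulate_cohort: requested more usable units than days in the study window")
    children[[i]] <- with_seed(seed + i, {
      simulate_child_record(sprintf("C%03d", i), nappa = pair[1], hr = pair[2],
                            study_days = study_days)
    })
  }
  structure(list(children = children, study_days = study_days), class = "study_cohort")
}

simulate_child_record <- function(child_id, nappa, hr, study_days) {
  usable_day <- seq_len(study_days) %in% sample(study_days, hr)
  hr_days <- data.frame(
    day = seq_len(study_days),
    mean_hr_bpm = ifelse(usable_day, rnorm(study_days, 125, 4), NA_real_),
    mean_sdrri_ms = ifelse(usable_day, rnorm(study_days, 35, 4), NA_real_),
    attached_hours = ifelse(usable_day, 8, 2)
  )
  nights <- if (nappa > 0) {
    data.frame(
      night_id = seq_len(nappa),
      duration_h = rep(9, nappa),
      prop_above_autocorr = runif(nappa, 0.4, 0.9),
      mean_resp_rate_bpm = rnorm(nappa, 25, 1.5),
      resp_rate_variance = runif(nappa, 2, 6),
      ultradian_period_min = runif(nappa, 45, 100)
    )
  } else {
    empty_nights_df()
  }
  child_record(child_id = child_id, hr_days = hr_days, nappa_nights = nights)
}

empty_nights_df <- function() {
  data.frame(night_id = integer(), duration_h = numeric(),
             prop_above_autocorr = numeric(), mean_resp_rate_bpm = numeric(),
             resp_rate_variance = numeric(), ultradian_period_min = numeric())
}
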