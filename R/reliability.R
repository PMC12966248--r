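# Per-child reliability statistics, usability determination, paired device
# comparison, precision planning and threshold sensitivity sweeps.

#' Child record and study cohort containers
#'
#' A `child_record` holds one child's per-day heart-rate-monitor summaries,
#' per-night respiration-monitor summaries and diary.  A `study_cohort` is a
#' list of child records plus the study window length in days.
#'
#' @param child_id unique identifier.
#' @param hr_days data frame with columns `day`, `mean_hr_bpm`,
#'   `mean_sdrri_ms`, `attached_hours` (one row per study day the monitor
#'   produced any data; `NA` metrics on unusable days).
#' @param nappa_nights data frame with columns `night_id`, `duration_h`,
#'   `prop_above_autocorr`, `mean_resp_rate_bpm`, `resp_rate_variance`,
#'   `ultradian_period_min` (one row per recorded night).
#' @param diary a [diary_log()] (optional).
#' @return `child_record()` returns a `child_record`; `study_cohort()` a
#'   `study_cohort`.
#' @export
child_record <- function(child_id, hr_days = NULL, nappa_nights = NULL, diary = NULL) {
  if (is.null(hr_days))
    hr_days <- data.frame(day = integer(), mean_hr_bpm = numeric(),
                          mean_sdrri_ms = numeric(), attached_hours = numeric())
  if (is.null(nappa_nights)) nappa_nights <- empty_nights_df()
  need_d <- c("day", "mean_hr_bpm", "mean_sdrri_ms", "attached_hours")
  need_n <- c("night_id", "duration_h")
  if (!all(need_d %in% names(hr_days)))
    validation_error("child_record: hr_days needs columns ", paste(need_d, collapse = ", "))
  if (!all(need_n %in% names(nappa_nights)))
    validation_error("child_record: nappa_nights needs columns ", paste(need_n, collapse = ", "))
  structure(list(child_id = as.character(child_id), hr_days = hr_days,
                 nappa_nights = nappa_nights, diary = diary),
            class = "child_record")
}

#' @param children list of `child_record` objects with unique ids.
#' @param study_days study window length in days (default 7).
#' @rdname child_record
#' @export
study_cohort <- function(children = list(), study_days = 7) {
  ids <- vapply(children, function(ch) ch$child_id, "")
  if (anyDuplicated(ids)) validation_error("study_cohort: duplicate child ids")
  structure(list(children = children, study_days = study_days),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d child(ren), %g-day study window\n",
              length(x$children), x$study_days))
  invisible(x)
}

#' Usability rules
#'
#' Thresholds deciding whether a monitor day or a respiration night counts as
#' usable.  The study reports usable-unit counts without printing its rule;
#' these defaults (>= 6 attached hours per usable day, >= 6 recorded hours
#' per usable night, 7-day denominator) are explicit configuration.
#'
#' @param min_attached_hours minimum attached wear per usable monitor day.
#' @param min_night_hours minimum recording duration per usable night.
#' @param study_days denominator for proportions.
#' @return A list of class `usability_rules`.
#' @export
usability_rules <- function(min_attached_hours = 6, min_night_hours = 6,
                            study_days = 7) {
  if (study_days <= 0) config_error("usability_rules: study_days must be > 0")
  structure(list(min_attached_hours = min_attached_hours,
                 min_night_hours = min_night_hours,
                 study_days = study_days),
            class = "usability_rules")
}

#' Count usable units for one child
#'
#' @param record a [child_record()].
#' @param rules a [usability_rules()].
#' @return List: `nappa_usable`, `hr_usable`, `denominator`, `nappa_prop`,
#'   `hr_prop`.
#' @examples
#' co <- simulate_cohort(1, list(c(7, 1)), seed = 1)
#' usable_units(co$children[[1]])  # proportions 1.00 and 1/7
#' @export
usable_units <- function(record, rules = usability_rules()) {
  stopifnot(inherits(record, "child_record"))
  if (rules$study_days <= 0) config_error("usable_units: zero denominator")
  nappa <- sum(record$nappa_nights$duration_h >= rules$min_night_hours, na.rm = TRUE)
  hr <- sum(record$hr_days$attached_hours >= rules$min_attached_hours, na.rm = TRUE)
  list(nappa_usable = nappa, hr_usable = hr, denominator = rules$study_days,
       nappa_prop = nappa / rules$study_days, hr_prop = hr / rules$study_days)
}

#' Per-child reliability table
#'
#' Across-unit mean, t-based 95% confidence interval and coefficient of
#' variation for each of the three key measures: daily mean heart rate, daily
#' mean HRV (SDRRI) and nightly ultradian period.  With a single unit the
#' mean is reported and CI/CV are undefined; with none, everything is.
#'
#' @param record a [child_record()].
#' @return Data frame with one row per metric (`HR`, `HRV`,
#'   `ultradian_period`) and columns `mean`, `ci_low`, `ci_high`,
#'   `cv_percent`, `n_units`.
#' @examples
#' rec <- child_record("P00X",
#'   hr_days = data.frame(day = 1:2, mean_hr_bpm = c(120, 126),
#'                        mean_sdrri_ms = NA_real_, attached_hours = 8))
#' reliability_table(rec)
#' @export
reliability_table <- function(record) {
  stopifnot(inherits(record, "child_record"))
  vals <- list(
    HR = record$hr_days$mean_hr_bpm,
    HRV = record$hr_days$mean_sdrri_ms,
    ultradian_period = record$nappa_nights$ultradian_period_min
  )
  rows <- lapply(names(vals), function(metric) {
    v <- vals[[metric]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      data.frame(metric = metric, mean = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, cv_percent = NA_real_, n_units = 0L)
    } else if (n == 1L) {
      data.frame(metric = metric, mean = v, ci_low = NA_real_,
                 ci_high = NA_real_, cv_percent = NA_real_, n_units = 1L)
    } else {
      m <- mean(v); s <- sd(v)
      half <- qt(0.975, n - 1) * s / sqrt(n)
      data.frame(metric = metric, mean = m, ci_low = m - half, ci_high = m + half,
                 cv_percent = 100 * s / m, n_units = n)
    }
  })
  do.call(rbind, rows)
}

#' Exact Wilcoxon signed-rank test of paired differences against zero
#'
#' Zero differences are dropped; absolute differences are ranked with either
#' ordinal (first-occurrence, `ties.method = "first"`) or average tie
#' handling; the statistic `T` is the smaller of the positive- and
#' negative-rank sums.  For `n <= exact_max` non-zero differences the
#' two-sided p-value comes from the exact subset-sum distribution over the
#' realized ranks (so it is conditional on the observed ties); beyond that, a
#' normal approximation with continuity correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param ties `"ordinal"` or `"average"`.
#' @param exact_max largest `n` for which the exact distribution is used.
#' @return List of class `signed_rank_test`: `statistic_T`, `p_value`,
#'   `n_nonzero`, `rank_sum_pos`, `rank_sum_neg`, `ties`, `reason` (`"ok"` or
#'   `"all_zero"`).
#' @export
signed_rank_test <- function(diffs, ties = c("ordinal", "average"), exact_max = 25) {
  ties <- match.arg(ties)
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  out <- function(T, p, pos, neg, reason) {
    structure(list(statistic_T = T, p_value = p, n_nonzero = n,
                   rank_sum_pos = pos, rank_sum_neg = neg,
                   ties = ties, reason = reason),
              class = "signed_rank_test")
  }
  if (n == 0L) return(out(NA_real_, NA_real_, NA_real_, NA_real_, "all_zero"))
  r <- rank(abs(d), ties.method = if (ties == "ordinal") "first" else "average")
  pos <- sum(r[d > 0]); neg <- sum(r[d < 0])
  T <- min(pos, neg)
  if (n <= exact_max) {
    p <- min(1, 2 * psignrank_ranks(T, r))
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (T + 0.5 - mu) / sigma
    p <- min(1, 2 * stats::pnorm(z))
  }
  out(T, p, pos, neg, "ok")
}

# P(W <= T) where W is the sum of a uniformly random subset of the given
# ranks (the exact null distribution of the signed-rank sum conditional on
# the realized ranks).  Ranks may be half-integers (average ties): everything
# is doubled to integers first.
psignrank_ranks <- function(T, ranks) {
  r2 <- round(ranks * 2)
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s + 1] = number of subsets with doubled-sum s
  f[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), f[seq_len(total + 1L - r)])
    f <- f + shifted
  }
  sum(f[seq_len(min(floor(T * 2), total) + 1L)]) / 2^length(ranks)
}

#' @export
print.signed_rank_test <- function(x, ...) {
  if (x$reason == "all_zero") {
    cat("<signed_rank_test> undefined: all differences zero\n")
  } else {
    cat(sprintf("<signed_rank_test> T = %g, p = %.4g (n = %d non-zero, %s ties)\n",
                x$statistic_T, x$p_value, x$n_nonzero, x$ties))
  }
  invisible(x)
}

#' Paired comparison of device success across a cohort
#'
#' For each child, the difference between the proportion of usable
#' respiration-monitor nights and usable heart-rate-monitor days is computed;
#' the signed-rank test then asks whether that difference departs from zero.
#'
#' @param cohort a [study_cohort()] (or [simulate_cohort()] output).
#' @param rules a [usability_rules()].
#' @param ties tie-handling mode passed to [signed_rank_test()].
#' @param proportions optional data frame with columns `nappa_prop` and
#'   `hr_prop` (and optionally `child_id`) to use directly instead of
#'   deriving proportions from the cohort -- used when feeding published
#'   per-child proportions through the test.
#' @return An object of class `device_comparison`: `per_child` data frame
#'   (`child_id`, `nappa_usable`, `nappa_prop`, `hr_usable`, `hr_prop`,
#'   `diff`), `statistic_T`, `p_value`, `n_nonzero`, `ties`, `reason`.
#' @export
compare_devices <- function(cohort = NULL, rules = usability_rules(),
                            ties = c("ordinal", "average"), proportions = NULL) {
  ties <- match.arg(ties)
  if (is.null(proportions)) {
    stopifnot(inherits(cohort, "study_cohort"))
    if (length(cohort$children) == 0L)
      config_error("compare_devices: empty cohort")
    per_child <- do.call(rbind, lapply(cohort$children, function(ch) {
      u <- usable_units(ch, rules)
      data.frame(child_id = ch$child_id, nappa_usable = u$nappa_usable,
                 nappa_prop = u$nappa_prop, hr_usable = u$hr_usable,
                 hr_prop = u$hr_prop)
    }))
  } else {
    if (!all(c("nappa_prop", "hr_prop") %in% names(proportions)))
      config_error("compare_devices: proportions needs columns nappa_prop, hr_prop")
    per_child <- data.frame(
      child_id = proportions$child_id %||% paste0("C", seq_len(nrow(proportions))),
      nappa_usable = proportions$nappa_usable %||% NA_real_,
      nappa_prop = proportions$nappa_prop,
      hr_usable = proportions$hr_usable %||% NA_real_,
      hr_prop = proportions$hr_prop)
  }
  per_child$diff <- per_child$nappa_prop - per_child$hr_prop
  test <- signed_rank_test(per_child$diff, ties = ties)
  structure(list(per_child = per_child, statistic_T = test$statistic_T,
                 p_value = test$p_value, n_nonzero = test$n_nonzero,
                 ties = ties, reason = test$reason),
            class = "device_comparison")
}

#' @export
print.device_comparison <- function(x, ...) {
  cat(sprintf("<device_comparison> %d children\n", nrow(x$per_child)))
  print(x$per_child, row.names = FALSE)
  if (x$reason == "all_zero") {
    cat("T undefined: all per-child differences are zero\n")
  } else {
    cat(sprintf("T = %g, p = %.3g (%s ties, n = %d non-zero)\n",
                x$statistic_T, x$p_value, x$ties, x$n_nonzero))
  }
  invisible(x)
}

#' Cohort roll-up of wear and usability counts
#'
#' One row per child: recorded and usable night counts, usable monitor days,
#' and the total attached wear in hours -- the quantities from which the
#' study's wear-summary and device-success tables are assembled.
#'
#' @param cohort a [study_cohort()].
#' @param rules a [usability_rules()].
#' @return Data frame with columns `child_id`, `nights_recorded`,
#'   `nights_usable`, `hr_days_usable`, `total_attached_h`.
#' @export
cohort_summary <- function(cohort, rules = usability_rules()) {
  stopifnot(inherits(cohort, "study_cohort"))
  if (length(cohort$children) == 0L) {
    return(data.frame(child_id = character(), nights_recorded = integer(),
                      nights_usable = integer(), hr_days_usable = integer(),
                      total_attached_h = numeric()))
  }
  do.call(rbind, lapply(cohort$children, function(ch) {
    u <- usable_units(ch, rules)
    data.frame(child_id = ch$child_id,
               nights_recorded = nrow(ch$nappa_nights),
               nights_usable = u$nappa_usable,
               hr_days_usable = u$hr_usable,
               total_attached_h = sum(ch$hr_days$attached_hours, na.rm = TRUE))
  }))
}

#' Precision half-width of a proportion estimate
#'
#' The a priori planning quantity `1.96 * sqrt(p * (1 - p) / n)`: the
#' half-width of the normal-approximation 95% interval for a proportion
#' estimated from `n` units.
#'
#' @param p anticipated proportion in `[0, 1]`.
#' @param n number of units, >= 1.
#' @return Half-width on the proportion scale.
#' @examples
#' precision_halfwidth(0.5, 100)  # 0.098
#' @export
precision_halfwidth <- function(p, n) {
  if (!is_scalar_num(p) || p < 0 || p > 1) config_error("precision_halfwidth: p must be in [0, 1]")
  if (!is_count(n) || n < 1) config_error("precision_halfwidth: n must be a count >= 1")
  1.96 * sqrt(p * (1 - p) / n)
}

#' Threshold sensitivity sweep
#'
#' Re-runs the wear, cardiac-quality and respiration summaries over a grid of
#' configuration overrides, producing one row per grid point so the effect of
#' each threshold on the headline quantities can be inspected.
#'
#' @param rr optional [rr_series()].
#' @param accel optional [accel_series()] (wear metrics need both streams).
#' @param night optional [respiration_night()].
#' @param cfg base [analysis_config()].
#' @param sweep named list of parameter vectors; names must be
#'   `analysis_config()` fields.  The full cross-product is evaluated.
#' @return Data frame: the grid columns plus, where computable,
#'   `wear_attached_s`, `wear_detached_s`, `error_rate_per_min`,
#'   `prop_hr_coverage`, `prop_hrv_coverage`, `n_flagged`,
#'   `prop_above_autocorr`, `ultradian_period_min`.
#' @export
threshold_sensitivity <- function(rr = NULL, accel = NULL, night = NULL,
                                  cfg = NULL, sweep = list()) {
  cfg <- as_config(cfg)
  if (length(sweep) == 0L) config_error("threshold_sensitivity: empty sweep grid")
  bad <- setdiff(names(sweep), names(cfg))
  if (length(bad))
    config_error("threshold_sensitivity: unknown config field(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(sweep, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- do.call(analysis_config, modifyList(unclass(cfg), as.list(grid[i, , drop = FALSE])))
    row <- grid[i, , drop = FALSE]
    if (!is.null(rr) && !is.null(accel)) {
      states <- suppressWarnings(classify_wear(rr, accel, cfg_i))
      ws <- wear_summary(states, rr, cfg_i)
      row$wear_attached_s <- ws$wear_attached_s
      row$wear_detached_s <- ws$wear_detached_s
      row$error_rate_per_min <- ws$error_rate_per_min
    }
    if (!is.null(rr)) {
      qr <- quality_report(rr, cfg_i)
      row$prop_hr_coverage <- qr$prop_hr_coverage
      row$prop_hrv_coverage <- qr$prop_hrv_coverage
      row$n_flagged <- length(qr$flagged_windows)
    }
    if (!is.null(night)) {
      row$prop_above_autocorr <- mean(quality_mask(night, cfg_i))
      row$ultradian_period_min <- ultradian_cycle(night, cfg_i)$period_min
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
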