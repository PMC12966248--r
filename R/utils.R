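# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.  All generator randomness flows through this; no function
# mutates global RNG state observably.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stop with a consistent configuration-error class so callers can distinguish
# bad inputs from bad data.
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("infantwear_config_error", "error")))
}

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("infantwear_validation_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Check a list of (start, end) windows: inside [0, duration), non-overlapping.
check_windows <- function(windows, duration_s, what) {
  if (length(windows) == 0L) return(invisible(TRUE))
  mat <- do.call(rbind, lapply(windows, function(w) as.numeric(w[1:2])))
  if (any(!is.finite(mat))) config_error(what, ": non-finite window bounds")
  if (any(mat[, 1] < 0) || any(mat[, 2] > duration_s) || any(mat[, 1] >= mat[, 2]))
    config_error(what, ": windows must satisfy 0 <= start < end <= duration_s")
  o <- order(mat[, 1])
  mat <- mat[o, , drop = FALSE]
  if (nrow(mat) > 1L && any(mat[-1, 1] < mat[-nrow(mat), 2]))
    config_error(what, ": windows overlap")
  invisible(TRUE)
}

# Positions recognised in the respiration stream.
POSITION_LEVELS <- c("supine", "prone", "left", "right", "upright", "unknown")

# Diary entry categories.
DIARY_CATEGORIES <- c("sleep", "nap", "feeding", "play_light", "play_intense",
                      "out_of_home", "device_event", "other")

WEAR_STATES <- c("worn_attached", "worn_detached", "not_worn")
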