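# Canonical on-disk formats: plain CSV, UTF-8, "." decimal, LF endings, one
# header line, preceded by "# key=value" comment lines carrying the ISO-8601
# start-time anchor (and sample rate where relevant).  Times in the body are
# seconds since the anchor.  Round-trips are lossless well below the declared
# 1 ms / 0.1 mg precision.

read_canonical_csv <- function(path, required_cols, numeric_cols) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[cumsum(!is_meta) == 0 & is_meta]  # leading comments only
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  body_start <- length(meta_lines) + 1L
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) validation_error(path, ": missing header line")
  df <- read.csv(text = paste(body, collapse = "\n"), colClasses = "character",
                 check.names = FALSE)
  extra <- setdiff(names(df), required_cols)
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    validation_error(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  # File line number of data row i (comments + header precede the data).
  line_of <- function(i) body_start + i
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      validation_error(path, " line ", line_of(bad[1]), ": non-numeric value \"",
                       df[[col]][bad[1]], "\" in column ", col)
    df[[col]] <- v
  }
  list(meta = meta, data = df[required_cols], line_of = line_of)
}

write_canonical_csv <- function(df, path, meta, digits = 6) {
  dir <- dirname(path)
  if (!dir.exists(dir)) validation_error("parent directory does not exist: ", dir)
  con <- file(path, open = "wb")  # binary => LF endings on every platform
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s=%s", nm, meta[[nm]]), con, sep = "\n")
  }
  num <- vapply(df, is.numeric, TRUE)
  for (col in names(df)[num]) {
    df[[col]] <- formatC(df[[col]], format = "f", digits = digits, drop0trailing = TRUE)
  }
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  if (nrow(df)) writeLines(do.call(paste, c(unname(df), sep = ",")), con, sep = "\n")
  invisible(path)
}

#' Read / write an R-R interval series
#'
#' Canonical CSV with columns `t_s,rr_ms` and a `# start_time=` comment line.
#' Reading validates positivity, strict monotonicity, and the beat-time /
#' interval continuity invariant (1 ms tolerance), naming the offending file
#' line; unknown columns produce a warning, not an error.
#'
#' @param path file path.
#' @param series an [rr_series()].
#' @param check_continuity passed to [rr_series()]; disable when reading a
#'   physiologically filtered stream.
#' @return `read_rr()` returns an [rr_series()]; `write_rr()` returns `path`
#'   invisibly.
#' @export
read_rr <- function(path, check_continuity = TRUE) {
  p <- read_canonical_csv(path, c("t_s", "rr_ms"), c("t_s", "rr_ms"))
  d <- p$data
  if (nrow(d)) {
    if (any(d$rr_ms <= 0))
      validation_error(path, " line ", p$line_of(which(d$rr_ms <= 0)[1]),
                       ": rr_ms must be positive")
    if (nrow(d) > 1L && any(diff(d$t_s) <= 0))
      validation_error(path, " line ", p$line_of(which(diff(d$t_s) <= 0)[1] + 1L),
                       ": t_s not strictly increasing")
  }
  rr_series(t_s = d$t_s, rr_ms = d$rr_ms,
            start_time = p$meta$start_time %||% "1970-01-01T00:00:00Z",
            check_continuity = check_continuity)
}

#' @rdname read_rr
#' @export
write_rr <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  write_canonical_csv(series$beats, path, list(start_time = series$start_time))
}

#' Read / write a tri-axial accelerometry series
#'
#' Canonical CSV with columns `ax_mg,ay_mg,az_mg`, plus `# start_time=` and
#' `# sample_rate_hz=` comment lines.
#'
#' @param path file path.
#' @param series an [accel_series()].
#' @return `read_accel()` returns an [accel_series()].
#' @export
read_accel <- function(path) {
  p <- read_canonical_csv(path, c("ax_mg", "ay_mg", "az_mg"),
                          c("ax_mg", "ay_mg", "az_mg"))
  rate <- suppressWarnings(as.numeric(p$meta$sample_rate_hz %||% "25"))
  if (is.na(rate) || rate <= 0)
    validation_error(path, ": invalid sample_rate_hz header")
  accel_series(ax_mg = p$data$ax_mg, ay_mg = p$data$ay_mg, az_mg = p$data$az_mg,
               sample_rate_hz = rate,
               start_time = p$meta$start_time %||% "1970-01-01T00:00:00Z")
}

#' @rdname read_accel
#' @export
write_accel <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  write_canonical_csv(series$samples, path,
                      list(start_time = series$start_time,
                           sample_rate_hz = format(series$sample_rate_hz)),
                      digits = 3)
}

#' Read / write one night of respiration-monitor output
#'
#' Canonical CSV with columns `t_s,resp_rate_bpm,autocorr,position` and a
#' `# start_time=` comment.  Autocorrelation values outside `[-1, 1]` are a
#' validation error; unrecognised position labels map to `"unknown"` with a
#' warning.
#'
#' @param path file path.
#' @param night a [respiration_night()].
#' @return `read_nappa()` returns a [respiration_night()].
#' @export
read_nappa <- function(path) {
  p <- read_canonical_csv(path, c("t_s", "resp_rate_bpm", "autocorr", "position"),
                          c("t_s", "resp_rate_bpm", "autocorr"))
  d <- p$data
  if (nrow(d) && any(d$autocorr < -1 | d$autocorr > 1))
    validation_error(path, " line ", p$line_of(which(d$autocorr < -1 | d$autocorr > 1)[1]),
                     ": autocorr outside [-1, 1]")
  respiration_night(t_s = d$t_s, resp_rate_bpm = d$resp_rate_bpm,
                    autocorr = d$autocorr, position = d$position,
                    start_time = p$meta$start_time %||% "1970-01-01T00:00:00Z")
}

#' @rdname read_nappa
#' @export
write_nappa <- function(night, path) {
  stopifnot(inherits(night, "respiration_night"))
  write_canonical_csv(night$samples, path, list(start_time = night$start_time))
}

#' Read / write a parent diary log
#'
#' Canonical CSV with columns `start,end,label,category` (ISO-8601 times).
#' An entry whose end precedes its start is a validation error; unknown
#' categories map to `"other"` with a warning.
#'
#' @param path file path.
#' @param diary a [diary_log()].
#' @return `read_diary()` returns a [diary_log()].
#' @export
read_diary <- function(path) {
  p <- read_canonical_csv(path, c("start", "end", "label", "category"), character())
  d <- p$data
  diary_log(start = d$start, end = d$end, label = d$label, category = d$category)
}

#' @rdname read_diary
#' @export
write_diary <- function(diary, path) {
  stopifnot(inherits(diary, "diary_log"))
  write_canonical_csv(as.data.frame(diary), path, list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
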