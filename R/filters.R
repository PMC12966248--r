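# Minimal IIR filtering toolkit: Butterworth band-pass design via the
# analog prototype -> band-pass transformation -> bilinear transform route,
# zero-phase application (forward-backward with reflective padding and
# steady-state initial conditions), and prominence-based peak detection.
# Kept in-package because no DSP package is available offline; designs were
# cross-checked against reference implementations during development and the
# tests assert the behavioural contract (pass-band gain, stop-band
# attenuation, zero phase shift).

# Polynomial coefficients (highest order first) from roots, real part taken
# after conjugate pairing.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- convolve_poly(p, c(1, -rt))
  p
}

convolve_poly <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- complex(n)
  for (i in seq_along(a)) {
    out[(i):(i + length(b) - 1L)] <- out[(i):(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Design a digital Butterworth band-pass filter
#'
#' @param order analog prototype order (the band-pass transformation doubles
#'   it); default 2.
#' @param w_low,w_high pass-band edges as fractions of the Nyquist frequency,
#'   `0 < w_low < w_high < 1`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @keywords internal
#' @export
butter_bandpass <- function(order = 2, w_low, w_high) {
  stopifnot(order >= 1, w_low > 0, w_low < w_high, w_high < 1)
  # Analog low-pass prototype: poles on the unit circle, no zeros, gain 1.
  k <- 1
  p <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  z <- complex(0)
  # Pre-warp edges (fs = 2 convention).
  fs <- 2
  w1 <- 2 * fs * tan(pi * w_low / fs)
  w2 <- 2 * fs * tan(pi * w_high / fs)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # Low-pass -> band-pass in the analog domain.
  degree <- length(p) - length(z)
  p_scaled <- p * bw / 2
  p_bp <- c(p_scaled + sqrt(p_scaled^2 - wo^2), p_scaled - sqrt(p_scaled^2 - wo^2))
  z_bp <- rep(0 + 0i, degree)
  k_bp <- k * bw^degree
  # Bilinear transform to the digital domain.
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

# Steady-state initial conditions for a step input (lfilter_zi construction):
# solving (I - A^T) zi = B for the companion-form state matrix.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b)))
  if (n == 1L) return(numeric(0))
  comp_t <- if (n == 2L) matrix(-a[2], 1L, 1L) else rbind(-a[-1], cbind(diag(n - 2L), rep(0, n - 2L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp_t), B)
}

# Direct-form II transposed IIR filter with initial state zi.
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  nz <- n - 1L
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1L) {
      z[1:(nz - 1L)] <- b[2:nz] * xi + z[2:nz] - a[2:nz] * yi
    }
    z[nz] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forwards and backwards with odd-reflection padding and
#' steady-state initial conditions, so that in-band components keep their
#' timing exactly (squared magnitude response, zero phase).
#'
#' @param b,a filter coefficients.
#' @param x signal.
#' @param padlen reflection padding length; defaults to
#'   `min(length(x) - 1, 3 * 10 * (max(length(a), length(b)) - 1))`, generous
#'   because the ultradian band is very low-frequency.
#' @return Filtered signal, same length as `x`.
#' @keywords internal
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- min(n - 1L, 30L * (ntaps - 1L))
  if (n <= ntaps) validation_error("filtfilt: signal too short for the filter")
  if (padlen > 0) {
    ext <- c(2 * x[1] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  } else {
    ext <- x
  }
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1L):(padlen + n)]
  y
}

#' Detect peaks with minimum separation and prominence
#'
#' Strict local maxima are filtered by topographic prominence (height above
#' the higher of the two bases toward the nearest higher ground on each
#' side), then thinned greedily from the highest peak down so that surviving
#' peaks are at least `min_separation` indices apart.
#'
#' @param x numeric signal.
#' @param min_separation minimum index distance between retained peaks.
#' @param min_prominence minimum prominence.
#' @return Integer indices of the retained peaks, increasing.
#' @keywords internal
#' @export
find_peaks <- function(x, min_separation = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), 0)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (j in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < min_separation)) keep[j] <- TRUE
  }
  sort(cand[keep])
}

peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1L) x[1:(i - 1L)] else numeric(0)
  right <- if (i < length(x)) x[(i + 1L):length(x)] else numeric(0)
  hi_l <- which(left > h)
  base_l <- if (length(hi_l)) min(left[(max(hi_l) + 1L):length(left)]) else min(c(left, h))
  hi_r <- which(right > h)
  base_r <- if (length(hi_r)) min(right[1:(min(hi_r) - 1L)]) else min(c(right, h))
  h - max(base_l, base_r)
}
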