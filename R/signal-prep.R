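#' Cochlear-spaced band edges
#'
#' Frequency band edges equidistant on the cochlear place map, used to build
#' the sub-bands of the wideband speech envelope. The position function is the
#' Greenwood map `f(x) = A (10^(a x) - k)` with the standard human constants;
#' edges are obtained by inverting an arithmetic progression in place `x`
#' between the positions of `f_lo` and `f_hi`.
#'
#' @param n_bands Number of bands (>= 1).
#' @param f_lo,f_hi Frequency range in Hz, `0 < f_lo < f_hi`.
#' @param A,a,k Greenwood constants; defaults are the conventional human
#'   values (A = 165.4 Hz, a = 2.1 per unit place, k = 0.88).
#' @return Numeric vector of `n_bands + 1` strictly increasing edges with
#'   `edges[1] == f_lo` and `edges[n_bands + 1] == f_hi`.
#' @examples
#' cochlear_band_edges(8, 100, 10000)
#' @export
cochlear_band_edges <- function(n_bands, f_lo = 100, f_hi = 10000,
                                A = 165.4, a = 2.1, k = 0.88) {
  if (!(n_bands >= 1) || n_bands != round(n_bands)) {
    stop("`n_bands` must be a positive integer", call. = FALSE)
  }
  if (!(f_lo > 0 && f_hi > f_lo)) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  pos <- function(f) log10(f / A + k) / a
  inv <- function(x) A * (10^(a * x) - k)
  edges <- inv(seq(pos(f_lo), pos(f_hi), length.out = n_bands + 1))
  edges[1] <- f_lo
  edges[n_bands + 1] <- f_hi
  edges
}

# Analytic signal via the one-sided spectrum: X(f) doubled on positive
# frequencies, DC and Nyquist kept, negative frequencies zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth band-pass: order-4 design applied forward and
# reverse (filtfilt), so the effective magnitude response is squared and the
# phase response is flat.
butter_bandpass_zero_phase <- function(x, fs, lo, hi, order = 4) {
  ny <- fs / 2
  if (!(lo > 0 && hi > lo && hi < ny)) {
    stop(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz (Nyquist)", lo, hi, ny),
      call. = FALSE
    )
  }
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

#' Wideband amplitude envelope of an audio signal
#'
#' Splits the audio into `n_bands` cochlear-spaced sub-bands, band-pass
#' filters each with a fourth-order zero-phase (forward-reverse) Butterworth
#' filter, takes the analytic amplitude per band, averages across bands, and
#' resamples the result to `out_fs` with a polyphase anti-aliased resampler.
#'
#' @param audio An [avp_ts] with `fs > 2 * f_hi`.
#' @param n_bands Number of cochlear bands (default 8).
#' @param f_lo,f_hi Band range in Hz (default 100-10,000).
#' @param out_fs Output sampling rate in Hz (default 250).
#' @return An [avp_ts] at `out_fs`; values are non-negative.
#' @export
wideband_envelope <- function(audio, n_bands = 8, f_lo = 100, f_hi = 10000,
                              out_fs = 250) {
  audio <- as_avp_ts(audio)
  if (audio$fs <= 2 * f_hi) {
    stop(sprintf(
      "audio sampling rate %g Hz must exceed twice the top band edge (2 x %g = %g Hz)",
      audio$fs, f_hi, 2 * f_hi
    ), call. = FALSE)
  }
  edges <- cochlear_band_edges(n_bands, f_lo, f_hi)
  env <- numeric(length(audio$values))
  for (b in seq_len(n_bands)) {
    xb <- butter_bandpass_zero_phase(audio$values, audio$fs, edges[b], edges[b + 1])
    env <- env + Mod(analytic_signal(xb))
  }
  env <- env / n_bands
  if (out_fs != audio$fs) {
    frac <- ratio_integers(out_fs, audio$fs)
    env <- signal::resample(env, frac[1], frac[2])
  }
  # polyphase ripple can undershoot zero by a hair; the envelope is a magnitude
  env <- pmax(env, 0)
  avp_ts(env, fs = out_fs, label = if (nzchar(audio$label)) paste0(audio$label, "_env") else "envelope")
}

# reduce p/q = a/b to smallest integers
ratio_integers <- function(a, b) {
  scale <- 1
  while (abs(a * scale - round(a * scale)) > 1e-9 || abs(b * scale - round(b * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) stop("cannot express resampling ratio as integer fraction", call. = FALSE)
  }
  p <- round(a * scale)
  q <- round(b * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-limited analytic signal
#'
#' Band-pass filters a series with a fourth-order Butterworth filter applied
#' forward and reverse (zero phase), then forms the analytic signal by Hilbert
#' transform. This is the canonical preprocessing for the phase estimators.
#'
#' @param x An [avp_ts] (or numeric vector with `fs`).
#' @param center Band center in Hz (default 5).
#' @param halfwidth Band half-width in Hz (default 2); the pass band is
#'   `center +/- halfwidth`.
#' @param fs Sampling rate, only if `x` is a bare vector.
#' @return An [avp_analytic].
#' @export
bandpass_analytic <- function(x, center = 5, halfwidth = 2, fs = NULL) {
  x <- as_avp_ts(x, fs)
  if (center - halfwidth <= 0) stop("`center - halfwidth` must be > 0", call. = FALSE)
  if (center + halfwidth >= x$fs / 2) {
    stop(sprintf(
      "band %g +/- %g Hz exceeds the Nyquist frequency %g Hz",
      center, halfwidth, x$fs / 2
    ), call. = FALSE)
  }
  xb <- butter_bandpass_zero_phase(x$values, x$fs, center - halfwidth, center + halfwidth)
  avp_analytic(analytic_signal(xb), fs = x$fs, band_center = center, band_halfwidth = halfwidth)
}

#' Unit-circle phase representation
#'
#' Normalises an analytic signal by its amplitude, giving a two-column
#' real representation of phase as points on the unit circle. Samples with
#' zero analytic amplitude (probability zero for real signals, but possible
#' for degenerate input) are flagged undefined and excluded downstream.
#'
#' @param s An [avp_analytic], or a complex vector.
#' @return An object of class `avp_phase`: fields `x`, `y` (unit-circle
#'   coordinates), `defined` (logical), `fs`.
#' @examples
#' p <- phase_2d(bandpass_analytic(avp_ts(rnorm(2500), fs = 250)))
#' range(p$x^2 + p$y^2)
#' @export
phase_2d <- function(s) {
  v <- if (inherits(s, "avp_analytic")) s$values else as.complex(s)
  amp <- Mod(v)
  ok <- amp > 0
  x <- y <- rep(NA_real_, length(v))
  x[ok] <- Re(v[ok]) / amp[ok]
  y[ok] <- Im(v[ok]) / amp[ok]
  structure(
    list(
      x = x, y = y, defined = ok,
      fs = if (inherits(s, "avp_analytic")) s$fs else NA_real_
    ),
    class = "avp_phase"
  )
}

#' @export
print.avp_phase <- function(x, ...) {
  cat(sprintf(
    "<avp_phase: %d samples (%d undefined)>\n",
    length(x$x), sum(!x$defined)
  ))
  invisible(x)
}

#' Align a stimulus with a lagged neural response
#'
#' Pairs `stimulus[t]` with `neural[t + lag]`, compensating for the
#' stimulus-to-brain conduction delay (positive lag means the neural signal
#' FOLLOWS the stimulus). The non-overlapping ends are truncated so both
#' outputs have equal length.
#'
#' @param stimulus,neural Numeric/complex vectors or [avp_ts] of equal length.
#' @param lag_ms Lag in milliseconds (>= 0; default 100).
#' @param fs Sampling rate in Hz, required for bare vectors.
#' @return List with `stimulus`, `neural` (trimmed vectors) and
#'   `lag_samples`.
#' @export
lag_align <- function(stimulus, neural, lag_ms = 100, fs = NULL) {
  sv <- if (inherits(stimulus, "avp_ts")) {
    fs <- stimulus$fs
    stimulus$values
  } else {
    stimulus
  }
  nv <- if (inherits(neural, "avp_ts")) neural$values else neural
  if (is.null(fs)) stop("`fs` required for bare vectors", call. = FALSE)
  if (length(sv) != length(nv)) stop("series must have equal length", call. = FALSE)
  if (lag_ms < 0) stop("`lag_ms` must be >= 0", call. = FALSE)
  k <- round(lag_ms * fs / 1000)
  n <- length(sv)
  if (k >= n) stop("lag exceeds series length", call. = FALSE)
  if (k == 0) {
    return(list(stimulus = sv, neural = nv, lag_samples = 0L))
  }
  list(
    stimulus = sv[seq_len(n - k)],
    neural = nv[(k + 1):n],
    lag_samples = as.integer(k)
  )
}

# Drop `t_edge` seconds from both ends; estimation windows exclude filter
# transients.
trim_edges <- function(x, fs, t_edge = 1) {
  k <- round(t_edge * fs)
  n <- length(x)
  if (2 * k >= n) stop("series too short to trim filter edges", call. = FALSE)
  x[(k + 1):(n - k)]
}
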