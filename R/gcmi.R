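#' Gaussian-copula rank normalisation
#'
#' Maps each column of a sample matrix through its empirical ranks to standard
#' normal quantiles: rank `r` of `n` goes to `qnorm(r / (n + 1))`, ties broken
#' by average rank. The transform preserves the dependence structure (copula)
#' while fixing every marginal to be Gaussian, which is what licenses the
#' closed-form Gaussian entropy downstream.
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @return A matrix of the same shape with class `avp_copula`.
#' @examples
#' copula_normalise(c(1, 2, 3))
#' @export
copula_normalise <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  out <- apply(x, 2, function(col) {
    if (max(col) == min(col)) {
      stop("constant column: ranks are undefined for MI estimation", call. = FALSE)
    }
    qnorm(rank(col, ties.method = "average") / (n + 1))
  })
  out <- matrix(out, nrow = n)
  colnames(out) <- colnames(x)
  class(out) <- c("avp_copula", class(out))
  out
}

# ln-space entropy terms of a d-dim Gaussian with covariance C (in nats,
# without the constant that cancels in MI): sum(log(diag(chol(C)))).
chol_logdet_half <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) {
    stop("singular joint covariance: variables are linearly dependent", call. = FALSE)
  })
  sum(log(diag(ch)))
}

#' Gaussian-copula mutual information between two variable blocks
#'
#' Computes `H(X) + H(Y) - H(X,Y)` from empirical covariances with the
#' Gaussian closed-form entropy, after (idempotent) copula normalisation of
#' each column. An analytic small-sample bias correction (digamma-based) is
#' applied to every entropy term by default, so null estimates are centred
#' near zero; estimates can be slightly negative at null and are reported as
#' computed. Covariances use 1/(n-1) normalisation. This is a lower-bound
#' estimate of the true MI.
#'
#' @param x,y Numeric matrices (or vectors) with the same number of rows;
#'   columns are the dimensions of each block.
#' @param bias_correct Apply the analytic bias correction (default `TRUE`).
#' @param copula Rank-normalise the inputs first (default `TRUE`; the rank
#'   transform is idempotent, so pre-normalised input is unharmed).
#' @return Mutual information in bits.
#' @examples
#' z <- matrix(rnorm(2000), ncol = 2)
#' mi_gg(z[, 1], z[, 2]) # near 0
#' @export
mi_gg <- function(x, y, bias_correct = TRUE, copula = TRUE) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of samples", call. = FALSE)
  n <- nrow(x)
  if (n < 10) stop("need at least 10 samples to estimate MI", call. = FALSE)
  if (copula) {
    x <- copula_normalise(x)
    y <- copula_normalise(y)
  }
  dx <- ncol(x)
  dy <- ncol(y)
  xy <- cbind(x, y)
  xy <- sweep(xy, 2, colMeans(xy))
  C <- crossprod(xy) / (n - 1)
  hx <- chol_logdet_half(C[seq_len(dx), seq_len(dx), drop = FALSE])
  hy <- chol_logdet_half(C[dx + seq_len(dy), dx + seq_len(dy), drop = FALSE])
  hxy <- chol_logdet_half(C)
  if (bias_correct) {
    d <- dx + dy
    psi <- digamma((n - seq_len(d)) / 2) / 2
    dterm <- (log(2) - log(n - 1)) / 2
    hx <- hx - dx * dterm - sum(psi[seq_len(dx)])
    hy <- hy - dy * dterm - sum(psi[seq_len(dy)])
    hxy <- hxy - d * dterm - sum(psi)
  }
  (hx + hy - hxy) / log(2)
}

#' Mutual information between two phase signals
#'
#' Copula-normalises the real and imaginary unit-circle coordinates of each
#' phase representation separately and applies the multivariate
#' Gaussian-copula estimator between the two 2-dimensional blocks. Samples
#' undefined in either signal are dropped pairwise.
#'
#' @param a,b [phase_2d()] representations of equal length.
#' @param bias_correct Passed to [mi_gg()].
#' @return Mutual information in bits.
#' @export
mi_phase <- function(a, b, bias_correct = TRUE) {
  stopifnot(inherits(a, "avp_phase"), inherits(b, "avp_phase"))
  if (length(a$x) != length(b$x)) stop("phase signals must have equal length", call. = FALSE)
  ok <- a$defined & b$defined
  if (sum(ok) < 10) stop("fewer than 10 jointly defined samples", call. = FALSE)
  mi_gg(cbind(a$x[ok], a$y[ok]), cbind(b$x[ok], b$y[ok]), bias_correct = bias_correct)
}

#' Spectral profile of phase mutual information
#'
#' Sweeps a set of band centers; at each, band-pass filters both series
#' (`center +/- halfwidth`, zero phase), forms unit-circle phase
#' representations, and estimates their mutual information. The first and
#' last second are excluded from estimation to avoid filter transients.
#'
#' @param u,v [avp_ts] series at the same sampling rate.
#' @param centers Band centers in Hz (default 3-20 Hz in 1-Hz steps).
#' @param halfwidth Band half-width in Hz (default 2).
#' @param bias_correct Passed to [mi_gg()].
#' @return A tibble of class `avp_mi_profile` with columns `frequency` (Hz)
#'   and `mi` (bits).
#' @export
spectral_mi_profile <- function(u, v, centers = seq(3, 20, by = 1), halfwidth = 2,
                                bias_correct = TRUE) {
  u <- as_avp_ts(u)
  v <- as_avp_ts(v)
  if (u$fs != v$fs) stop("series must share a sampling rate", call. = FALSE)
  if (any(centers <= halfwidth) || any(centers + halfwidth >= u$fs / 2)) {
    stop("band centers must lie within (halfwidth, fs/2 - halfwidth)", call. = FALSE)
  }
  mi <- vapply(centers, function(fc) {
    au <- bandpass_analytic(u, fc, halfwidth)
    av <- bandpass_analytic(v, fc, halfwidth)
    pu <- phase_2d(trim_analytic(au))
    pv <- phase_2d(trim_analytic(av))
    mi_phase(pu, pv, bias_correct = bias_correct)
  }, numeric(1))
  new_mi_profile(tibble(frequency = as.numeric(centers), mi = mi), axis = "frequency")
}

trim_analytic <- function(s, t_edge = 1) {
  avp_analytic(trim_edges(s$values, s$fs, t_edge), s$fs, s$band_center, s$band_halfwidth)
}

new_mi_profile <- function(tbl, axis) {
  structure(tbl, class = c("avp_mi_profile", class(tbl)), axis = axis)
}

#' Delayed mutual information profile
#'
#' MI between the phase of `u` at time `t` and the phase of `v` at `t + lag`
#' over a grid of lags; positive MI at positive lags means `u` carries
#' information about the FUTURE of `v`. Both series are band-pass filtered
#' once (`band_center +/- band_halfwidth`), edge-trimmed, then re-aligned per
#' lag.
#'
#' @param u,v [avp_ts] series at the same sampling rate (or [avp_analytic]
#'   already filtered).
#' @param lags_ms Lag grid in milliseconds (default 0-500 ms in 20 ms steps,
#'   26 points).
#' @param band_center,band_halfwidth Band in Hz (defaults 5 and 2) applied
#'   when the inputs are raw time series.
#' @param bias_correct Passed to [mi_gg()].
#' @return A tibble of class `avp_mi_profile` with columns `lag_ms` and `mi`
#'   (bits), and attribute `mean_mi` (the across-lag average).
#' @export
delayed_mi <- function(u, v, lags_ms = seq(0, 500, by = 20),
                       band_center = 5, band_halfwidth = 2, bias_correct = TRUE) {
  au <- if (inherits(u, "avp_analytic")) u else bandpass_analytic(as_avp_ts(u), band_center, band_halfwidth)
  av <- if (inherits(v, "avp_analytic")) v else bandpass_analytic(as_avp_ts(v), band_center, band_halfwidth)
  if (au$fs != av$fs) stop("series must share a sampling rate", call. = FALSE)
  fs <- au$fs
  uu <- trim_edges(au$values, fs)
  vv <- trim_edges(av$values, fs)
  if (max(lags_ms) / 1000 >= length(uu) / fs) {
    stop("maximum lag exceeds the series duration", call. = FALSE)
  }
  mi <- vapply(lags_ms, function(lag) {
    al <- lag_align(uu, vv, lag_ms = lag, fs = fs)
    mi_phase(phase_2d(al$stimulus), phase_2d(al$neural), bias_correct = bias_correct)
  }, numeric(1))
  out <- new_mi_profile(tibble(lag_ms = as.numeric(lags_ms), mi = mi), axis = "lag_ms")
  attr(out, "mean_mi") <- mean(mi)
  out
}

#' Plug-in discrete mutual information
#'
#' Direct plug-in estimate from joint category counts, in bits. Used as an
#' analytic unit check: a fair binary variable observed with itself carries
#' exactly 1 bit — observing one value halves the uncertainty about the
#' other (the factor-2 reading of a bit).
#'
#' @param x,y Discrete vectors (factors or coercible) of equal length.
#' @return MI in bits.
#' @examples
#' coin <- rep(c(0, 1), 50)
#' mi_plugin_discrete(coin, coin) # exactly 1
#' @export
mi_plugin_discrete <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  j <- table(x, y) / length(x)
  px <- rowSums(j)
  py <- colSums(j)
  e <- outer(px, py)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / e[nz]))
}
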