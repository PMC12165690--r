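#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at 6 s, undershoot
#' peak at 16 s and a peak-to-undershoot amplitude ratio of 6, sampled on a
#' 32 s causal kernel and scaled to unit peak.
#'
#' @param dt Sampling step of the kernel in seconds.
#' @param length_s Kernel length in seconds (default 32).
#' @return Numeric vector of kernel samples at `t = 0, dt, 2*dt, ...`.
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  stopifnot(dt > 0, length_s > dt)
  t <- seq(0, length_s, by = dt)
  # gamma(shape = a, scale = 1) has its mode at a - 1
  h <- stats::dgamma(t, shape = 7, scale = 1) -
    stats::dgamma(t, shape = 17, scale = 1) / 6
  h / max(h)
}

#' Convolve region signals with the canonical HRF
#'
#' Causal convolution of each region's timecourse (typically a band-limited
#' amplitude envelope) with the canonical double-gamma kernel sampled at the
#' signal's own rate, trimmed to the input length. Used to create
#' hemodynamically smoothed versions of fast signals for cross-modal
#' comparison at matched temporal characteristics.
#'
#' @param signals A [region_signal_set()].
#' @param tr Unused by the convolution itself; retained so callers can record
#'   the TR context the convolved signal will be sampled at. Default `NULL`.
#' @return A `region_signal_set` of identical shape.
#' @export
hrf_convolve <- function(signals, tr = NULL) {
  stopifnot(inherits(signals, "region_signal_set"))
  k <- canonical_hrf(dt = 1 / signals$fs)
  x <- signals$values
  n <- ncol(x)
  # FFT-based linear convolution, causal, trimmed to input length
  m <- n + length(k) - 1L
  kf <- stats::fft(c(k, rep(0, m - length(k))))
  out <- t(apply(x, 1L, function(row) {
    xf <- stats::fft(c(row, rep(0, m - n)))
    Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / m
  }))
  signals$values <- out
  rownames(signals$values) <- signals$region_labels
  signals
}
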