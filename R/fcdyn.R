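# Frame-wise functional connectivity for both modalities.
#
# The fast (electrophysiology-like) modality is band-passed, Hilbert
# transformed, and summarized per TR-length window as amplitude coupling
# (mean product of globally z-scored envelopes) or phase coupling (phase
# locking value). The slow (BOLD-like) modality uses edge time series:
# per-frame products of globally z-scored region signals, whose temporal
# mean equals the Pearson correlation matrix.

#' Zero-phase Chebyshev type II band-pass filter
#'
#' Fourth-order Chebyshev type II design with 40 dB stopband attenuation and
#' stopband edges at the band limits, applied with zero phase (the squared
#' magnitude response, equivalent to forward-backward filtering) so phase
#' integrity is preserved for downstream phase-locking estimates, with
#' doubled stopband attenuation. The response is applied in the frequency
#' domain, which is exact up to circular boundary handling; boundary frames
#' are dropped downstream by the windowing anyway.
#'
#' @param signals A fast-modality [region_signal_set()].
#' @param band A [band_spec()]; `high` must be below the Nyquist frequency.
#' @return A band-limited `region_signal_set` carrying `band`.
#' @export
bandpass <- function(signals, band) {
  stopifnot(inherits(signals, "region_signal_set"), inherits(band, "band_spec"))
  if (signals$modality != "fast") stop("bandpass expects the fast modality", call. = FALSE)
  nyq <- signals$fs / 2
  if (band$high >= nyq) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", band$high, nyq),
         call. = FALSE)
  }
  flt <- signal::cheby2(4, Rp = 40, W = c(band$low, band$high) / nyq, type = "pass")
  n <- ncol(signals$values)
  zi <- exp(-1i * 2 * pi * (seq_len(n) - 1L) / n)
  h2 <- Mod(polyeval(flt$b, zi) / polyeval(flt$a, zi))^2
  signals$values <- t(apply(signals$values, 1L, function(row) {
    Re(stats::fft(stats::fft(row) * h2, inverse = TRUE)) / n
  }))
  rownames(signals$values) <- signals$region_labels
  signals$band <- band
  signals
}

# Horner evaluation of polynomial with coefficients in decreasing power
# (the filter-coefficient convention) at complex points z
polyeval <- function(coef, z) {
  acc <- rep(coef[1] + 0i, length(z))
  for (c_k in coef[-1]) acc <- acc * z + c_k
  acc
}

#' Hilbert envelope and unwrapped instantaneous phase
#'
#' Computes the analytic signal of each (band-limited) region timecourse via
#' the frequency-domain Hilbert transform and returns its amplitude envelope
#' and unwrapped phase. All-zero channels have no defined phase and are
#' rejected.
#'
#' @param signals A band-limited [region_signal_set()].
#' @return List with elements `envelope` and `phase`, both `region_signal_set`s.
#' @export
hilbert_env_phase <- function(signals) {
  stopifnot(inherits(signals, "region_signal_set"))
  n <- ncol(signals$values)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- signals; phs <- signals
  for (r in seq_len(nrow(signals$values))) {
    x <- signals$values[r, ]
    if (all(x == 0)) {
      stop(sprintf("channel %s is identically zero: phase undefined",
                   signals$region_labels[r]), call. = FALSE)
    }
    analytic <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
    env$values[r, ] <- Mod(analytic)
    phs$values[r, ] <- unwrap_phase(Arg(analytic))
  }
  list(envelope = env, phase = phs)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' TR-grid window specification for fast-modality FC
#'
#' Windows of length `L = tr` seconds (`N = round(tr * fs)` samples) centered
#' on the TR sampling grid of the slow modality: frame `k` is centered at
#' `(k - 1) * tr` seconds from the start of the recording. Frames whose full
#' window does not fit inside the recording are dropped.
#'
#' @param tr Repetition time in seconds.
#' @param fs Fast-modality sampling rate in Hz.
#' @param n_samples Number of fast-modality samples available.
#' @return List with `n_per_window`, `frame_index`, and per-frame start indices.
#' @export
window_spec <- function(tr, fs, n_samples) {
  n_win <- round(tr * fs)
  n_frames <- floor(n_samples / (tr * fs))
  centers <- (seq_len(n_frames) - 1L) * tr
  starts <- round(centers * fs - n_win / 2) + 1L
  ok <- starts >= 1L & (starts + n_win - 1L) <= n_samples
  list(n_per_window = as.integer(n_win),
       frame_index = which(ok),
       starts = as.integer(starts[ok]),
       tr = tr, fs = fs)
}

#' Amplitude-coupling edge series from band-limited envelopes
#'
#' For every TR-grid frame and region pair (i, j), the mean over the in-window
#' samples of the product of the two envelopes after global z-scoring (each
#' envelope standardized over the whole recording, population convention).
#'
#' @param envelope Envelope `region_signal_set` from [hilbert_env_phase()].
#' @param tr Repetition time in seconds defining the window length.
#' @return An [edge_frame_series()] with `coupling = "amp"`.
#' @export
eeg_fc_amp <- function(envelope, tr) {
  stopifnot(inherits(envelope, "region_signal_set"))
  x <- envelope$values
  for (r in seq_len(nrow(x))) {
    if (stats::sd(x[r, ]) == 0) {
      stop(sprintf("zero-variance envelope in channel %s", envelope$region_labels[r]),
           call. = FALSE)
    }
    x[r, ] <- zscore_pop(x[r, ])
  }
  win <- window_spec(tr, envelope$fs, ncol(x))
  ei <- edge_index(nrow(x))
  frames <- matrix(0, length(win$starts), nrow(ei))
  idx <- outer(seq_len(win$n_per_window) - 1L, win$starts, `+`)
  for (k in seq_along(win$starts)) {
    seg <- x[, idx[, k], drop = FALSE]
    prod_mat <- tcrossprod(seg) / win$n_per_window
    frames[k, ] <- upper_tri_vec(prod_mat)
  }
  edge_frame_series(frames, n_regions = nrow(x), tr = tr,
                    frame_index = win$frame_index, coupling = "amp",
                    band = envelope$band)
}

#' Phase-coupling (phase-locking value) edge series
#'
#' For every TR-grid frame and region pair, the modulus of the mean unit
#' phasor of the instantaneous phase difference over the in-window samples:
#' the phase-locking value, in `[0, 1]`, equal to 1 iff the phase difference
#' is constant within the window.
#'
#' @param phase Unwrapped-phase `region_signal_set` from [hilbert_env_phase()].
#' @param tr Repetition time in seconds defining the window length.
#' @return An [edge_frame_series()] with `coupling = "phase"`.
#' @export
eeg_fc_phase <- function(phase, tr) {
  stopifnot(inherits(phase, "region_signal_set"))
  x <- phase$values
  win <- window_spec(tr, phase$fs, ncol(x))
  ei <- edge_index(nrow(x))
  frames <- matrix(0, length(win$starts), nrow(ei))
  idx <- outer(seq_len(win$n_per_window) - 1L, win$starts, `+`)
  z <- exp(1i * x)
  for (k in seq_along(win$starts)) {
    seg <- z[, idx[, k], drop = FALSE]
    # mean over window of exp(i * (phi_i - phi_j)) = (1/N) * seg %*% Conj(t(seg))
    plv <- Mod(tcrossprod(seg, Conj(seg))) / win$n_per_window
    frames[k, ] <- pmin(upper_tri_vec(plv), 1)
  }
  edge_frame_series(frames, n_regions = nrow(x), tr = tr,
                    frame_index = win$frame_index, coupling = "phase",
                    band = phase$band)
}

#' BOLD edge time series
#'
#' Per-frame products of globally z-scored region signals (population
#' z-scoring), one connectome frame per TR. The temporal mean of each edge's
#' timecourse equals the full-series Pearson correlation of the two regions.
#'
#' @param bold A slow-modality [region_signal_set()] sampled at TR.
#' @param tr Repetition time in seconds (defaults to `1 / bold$fs`).
#' @return An [edge_frame_series()] with `coupling = "bold"`.
#' @export
fmri_edge_series <- function(bold, tr = 1 / bold$fs) {
  stopifnot(inherits(bold, "region_signal_set"))
  if (bold$modality != "slow") stop("fmri_edge_series expects the slow modality", call. = FALSE)
  x <- bold$values
  if (ncol(x) < 8L) stop("need at least 8 frames", call. = FALSE)
  for (r in seq_len(nrow(x))) {
    if (stats::sd(x[r, ]) == 0) {
      stop(sprintf("zero-variance region %s", bold$region_labels[r]), call. = FALSE)
    }
    x[r, ] <- zscore_pop(x[r, ])
  }
  ei <- edge_index(nrow(x))
  frames <- x[ei$i, , drop = FALSE] * x[ei$j, , drop = FALSE]
  edge_frame_series(t(frames), n_regions = nrow(x), tr = tr,
                    coupling = "bold")
}

#' Apply the hemodynamic shift to a BOLD edge series
#'
#' Compensates the lag between neural activity and the hemodynamic response
#' by re-indexing the BOLD-derived frames backwards in time: after a shift by
#' `lag` seconds, the frame paired with electrophysiology frame `k` is the
#' BOLD frame originally at `k + lag / tr`. The lag must be an integer
#' multiple of TR; overhanging frames are dropped.
#'
#' @param frames An [edge_frame_series()].
#' @param lag Shift in seconds (positive shifts the series backwards in time).
#' @param tr Repetition time in seconds.
#' @return The shifted `edge_frame_series` with `shifted = TRUE`.
#' @export
apply_hemodynamic_shift <- function(frames, lag, tr = frames$tr) {
  stopifnot(inherits(frames, "edge_frame_series"))
  k <- lag / tr
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("lag (%g s) must be an integer multiple of TR (%g s); use e.g. %g or %g s",
                 lag, tr, floor(k) * tr, ceiling(k) * tr), call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k == 0L) { frames$shifted <- TRUE; return(frames) }
  n <- nrow(frames$frames)
  if (abs(k) >= n) stop("lag exceeds the recording length", call. = FALSE)
  if (k > 0) sel <- (k + 1L):n else sel <- 1L:(n + k)
  frames$frames <- frames$frames[sel, , drop = FALSE]
  frames$frame_index <- frames$frame_index[sel] - k
  frames$shifted <- TRUE
  frames
}

#' Static (time-averaged) connectome of an edge series
#'
#' @param frames An [edge_frame_series()].
#' @return Numeric edge vector: the per-edge temporal mean.
#' @export
static_fc <- function(frames) {
  stopifnot(inherits(frames, "edge_frame_series"))
  colMeans(frames$frames)
}
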