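# Fourier phase-randomization surrogates.
#
# All constructions use conjugate-symmetric ("Hermitian") random phases so the
# inverse transform is real to machine precision and the amplitude spectrum is
# preserved exactly. A random phase field theta is antisymmetrized as
# phi(k) = theta(k) - theta(-k), which forces phi = 0 at the DC and
# self-conjugate (Nyquist) frequencies.

neg_index <- function(n) c(1L, if (n > 1L) n:2L)

hermitian_phases_1d <- function(n) {
  theta <- stats::runif(n, 0, 2 * pi)
  theta - theta[neg_index(n)]
}

hermitian_phases_2d <- function(nr, nc) {
  theta <- matrix(stats::runif(nr * nc, 0, 2 * pi), nr, nc)
  theta - theta[neg_index(nr), neg_index(nc), drop = FALSE]
}

# apply given conjugate-symmetric phases to a real matrix in 2D Fourier space
apply_phases_2d <- function(mat, phases) {
  f <- stats::fft(mat) * exp(1i * phases)
  Re(stats::fft(f, inverse = TRUE)) / length(mat)
}

#' Spatial phase permutation of a connectivity matrix
#'
#' Generates a spatial-null surrogate of a symmetric connectivity matrix by
#' randomizing the phases of its 2D Fourier transform while preserving the
#' amplitude spectrum (hence the mean and total variance). The randomized
#' field is real by construction; because phase randomization does not
#' preserve matrix symmetry, the surrogate is then re-symmetrized by
#' averaging with its transpose (disable with `resymmetrize = FALSE` to
#' inspect the raw spectrum-preserving field).
#'
#' @param fc Square symmetric numeric matrix (a connectivity matrix).
#' @param seed Optional integer seed for reproducibility.
#' @param resymmetrize Average the surrogate with its transpose (default TRUE).
#' @return A real matrix of the same dimension as `fc`.
#' @export
spatial_phase_permute_fc <- function(fc, seed = NULL, resymmetrize = TRUE) {
  stopifnot(is.matrix(fc), is.numeric(fc))
  if (nrow(fc) != ncol(fc)) stop("input must be square", call. = FALSE)
  if (!all(is.finite(fc))) stop("input must be finite", call. = FALSE)
  fc <- (fc + t(fc)) / 2
  if (!is.null(seed)) set.seed(seed)
  out <- apply_phases_2d(fc, hermitian_phases_2d(nrow(fc), ncol(fc)))
  if (resymmetrize) out <- (out + t(out)) / 2
  out
}

#' Temporal phase permutation of an edge-frame series
#'
#' Fourier phase-randomizes every edge timecourse independently, preserving
#' each edge's amplitude spectrum and leaving the DC component untouched, so
#' the static (time-averaged) connectome is preserved exactly while the
#' dynamic frame-to-frame patterns are destroyed.
#'
#' @param frames An [edge_frame_series()] with at least 8 frames.
#' @param seed Optional integer seed.
#' @return A surrogate `edge_frame_series` of identical shape.
#' @export
temporal_phase_permute_edges <- function(frames, seed = NULL) {
  stopifnot(inherits(frames, "edge_frame_series"))
  n <- nrow(frames$frames)
  if (n < 8L) stop("need at least 8 frames", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- frames$frames
  out <- matrix(0, n, ncol(x))
  for (e in seq_len(ncol(x))) {
    phi <- hermitian_phases_1d(n)
    f <- stats::fft(x[, e]) * exp(1i * phi)
    out[, e] <- Re(stats::fft(f, inverse = TRUE)) / n
  }
  frames$frames <- out
  frames
}

#' Phase-randomize a binary multi-frequency CRP
#'
#' Spatial null for binary cross-modal recurrence plots: each band layer is
#' treated as a real 0/1 field, phase-randomized in 2D Fourier space, and
#' re-binarized at the quantile that exactly preserves that layer's count of
#' significant entries (the quantity the on-/off-diagonal ratio conditions
#' on). The multi-frequency union layer is recomputed from the surrogate
#' band layers. Layers with no significant entries are returned unchanged.
#'
#' @param mfcrp A `multifreq_crp` object (see [overlay_bands()]), or a single
#'   logical matrix.
#' @param seed Optional integer seed.
#' @return Surrogate of the same class and shape.
#' @export
phase_randomize_crp <- function(mfcrp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(mfcrp) && is.logical(mfcrp)) {
    return(randomize_binary_layer(mfcrp))
  }
  stopifnot(inherits(mfcrp, "multifreq_crp"))
  mfcrp$layers <- lapply(mfcrp$layers, randomize_binary_layer)
  mfcrp$union <- Reduce(`|`, mfcrp$layers)
  mfcrp
}

randomize_binary_layer <- function(layer) {
  k <- sum(layer)
  if (k == 0L || k == length(layer)) return(layer)
  field <- apply_phases_2d(layer + 0, hermitian_phases_2d(nrow(layer), ncol(layer)))
  # threshold at the value whose exceedance count equals the original count;
  # ties broken by (stable) order so the count is preserved exactly
  ord <- order(field, decreasing = TRUE)
  out <- matrix(FALSE, nrow(layer), ncol(layer))
  out[ord[seq_len(k)]] <- TRUE
  out
}
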