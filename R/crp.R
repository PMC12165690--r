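# Cross-modal recurrence plots: all-pairs spatial correlation between
# slow-modality (fMRI) and band-specific fast-modality (EEG) connectome
# frames, entrywise permutation significance against spatially
# phase-permuted FC matrices, BH-FDR binarization, and the multi-frequency
# overlay.

#' Analysis configuration defaults
#'
#' @param q FDR level for CRP binarization (default 0.05).
#' @param n_perm Number of spatial phase permutations per band (default 100).
#' @param shifts Diagonal shifts in TR for the convergence profile
#'   (default -5..5).
#' @param prior_scale Cauchy prior scale of the Bayesian paired test
#'   (default 0.707).
#' @param n_null_crp Number of CRP-randomization surrogates for the ratio
#'   null (default 100).
#' @param n_surrogate_states Number of phase-permutation surrogates for the
#'   state dissociability test (default 50).
#' @return A named list of settings.
#' @export
analysis_config <- function(q = 0.05, n_perm = 100L, shifts = -5:5,
                            prior_scale = 0.707, n_null_crp = 100L,
                            n_surrogate_states = 50L) {
  stopifnot(q > 0, q < 1, n_perm >= 20L, n_null_crp >= 20L)
  list(q = q, n_perm = as.integer(n_perm), shifts = as.integer(shifts),
       prior_scale = prior_scale, n_null_crp = as.integer(n_null_crp),
       n_surrogate_states = as.integer(n_surrogate_states))
}

#' Cross-modal spatial correlation matrix
#'
#' Entry (a, b) is the Pearson correlation, across the shared edge set,
#' between slow-modality connectome frame `a` and fast-modality connectome
#' frame `b`: the real-valued recurrence matrix underlying the CRP.
#'
#' @param fmri,eeg [edge_frame_series()] objects over the same edge set.
#' @return `S_f x S_e` numeric matrix of correlations.
#' @export
cross_modal_correlation <- function(fmri, eeg) {
  stopifnot(inherits(fmri, "edge_frame_series"), inherits(eeg, "edge_frame_series"))
  if (fmri$n_regions != eeg$n_regions) {
    stop("edge-order mismatch: series derive from different region sets", call. = FALSE)
  }
  if (ncol(fmri$frames) < 8L) stop("need at least 8 edges", call. = FALSE)
  stats::cor(t(fmri$frames), t(eeg$frames))
}

# spatially phase-permute every frame of an edge series at once.
# Each frame is re-assembled to its symmetric R x R form (zero diagonal),
# phase-randomized in 2D Fourier space with conjugate-symmetric phases,
# re-symmetrized by averaging with the transpose, and collapsed back to the
# upper-triangle edge vector. Implemented with DFT-matrix products batched
# over frames.
spatial_permute_frame_stack <- function(frames, n_regions) {
  pre <- frame_fft2_stack(frames, n_regions)
  permute_from_fft2(pre)
}

# forward 2D DFT of every frame's symmetric R x R form (zero diagonal),
# computed once and reused across permutations
frame_fft2_stack <- function(frames, n_regions) {
  R <- n_regions
  Tn <- nrow(frames)
  dft <- exp(-2i * pi * outer(0:(R - 1), 0:(R - 1)) / R)
  maps <- edge_cell_maps(R)
  # stack frames as R x (R * T) via the cell -> edge index map (diagonal = 0)
  fr2 <- cbind(frames, 0)
  stack <- t(fr2[, maps$cell_to_edge, drop = FALSE])
  dim(stack) <- c(R, R * Tn)
  f1 <- dft %*% stack                       # DFT over rows, all frames at once
  dim(f1) <- c(R, R, Tn)
  f1 <- aperm(f1, c(2, 1, 3))
  dim(f1) <- c(R, R * Tn)
  f2 <- dft %*% f1                          # DFT over columns
  dim(f2) <- c(R, R, Tn)
  f2 <- aperm(f2, c(2, 1, 3))               # back to row-major frames
  list(f2 = f2, R = R, Tn = Tn, idft = Conj(dft), maps = maps,
       neg = neg_index(R))
}

# draw conjugate-symmetric random phases per frame, invert, re-symmetrize,
# return surrogate frames (T x E)
permute_from_fft2 <- function(pre) {
  R <- pre$R; Tn <- pre$Tn
  theta <- array(stats::runif(R * R * Tn, 0, 2 * pi), c(R, R, Tn))
  phi <- theta - theta[pre$neg, pre$neg, , drop = FALSE]
  f2 <- pre$f2 * exp(1i * phi)
  dim(f2) <- c(R, R * Tn)
  g1 <- pre$idft %*% f2
  dim(g1) <- c(R, R, Tn)
  g1 <- aperm(g1, c(2, 1, 3))
  dim(g1) <- c(R, R * Tn)
  g2 <- pre$idft %*% g1
  dim(g2) <- c(R, R, Tn)
  g2 <- Re(aperm(g2, c(2, 1, 3))) / R^2
  # re-symmetrize and pull the upper triangle for all frames at once
  dim(g2) <- c(R * R, Tn)
  t((g2[pre$maps$pos_upper, , drop = FALSE] +
       g2[pre$maps$pos_lower, , drop = FALSE]) / 2)
}

edge_cell_maps <- function(R) {
  ei <- edge_index(R)
  edge_id <- matrix(0L, R, R)
  edge_id[cbind(ei$i, ei$j)] <- seq_len(nrow(ei))
  edge_id[cbind(ei$j, ei$i)] <- seq_len(nrow(ei))
  n_edges <- nrow(ei)
  cell_to_edge <- as.vector(edge_id)
  cell_to_edge[cell_to_edge == 0L] <- n_edges + 1L # diagonal -> zero column
  list(cell_to_edge = cell_to_edge,
       pos_upper = (ei$j - 1L) * R + ei$i,
       pos_lower = (ei$i - 1L) * R + ei$j)
}

# standardize rows to zero mean and unit norm so that tcrossprod() of two
# such matrices yields the row-by-row Pearson correlation matrix
normalize_rows <- function(m) {
  c0 <- m - rowMeans(m)
  c0 / sqrt(rowSums(c0^2))
}

#' Entrywise permutation test of the cross-modal correlation matrix
#'
#' Builds the null distribution of every CRP entry by spatially
#' phase-permuting the slow-modality FC matrix at the corresponding
#' timepoint ([spatial_phase_permute_fc()] applied frame-wise) and
#' recomputing the full null recurrence matrix; `n_perm` null matrices are
#' generated once and each entry is compared to its own `n_perm` null
#' values. One-tailed empirical p for positive convergence:
#' `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)`; entries with
#' non-positive observed correlation are assigned p = 1 (anti-correlated
#' epochs are excluded by design).
#'
#' @param fmri,eeg [edge_frame_series()] objects over the same edge set.
#' @param n_perm Number of permutations (>= 20).
#' @param seed Optional integer seed.
#' @param positive_only Assign p = 1 to entries with non-positive observed
#'   correlation (default TRUE, the analysis convention); set FALSE to
#'   obtain the raw rank-based p for calibration checks.
#' @return List with `r` (observed matrix) and `p` (empirical p-values).
#' @export
entrywise_null_test <- function(fmri, eeg, n_perm = 100L, seed = NULL,
                                positive_only = TRUE) {
  stopifnot(n_perm >= 20L)
  if (fmri$n_regions < 4L) {
    stop("need at least 4 regions for the 2D spatial permutation null", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- cross_modal_correlation(fmri, eeg)
  eeg_n <- normalize_rows(eeg$frames)
  pre <- frame_fft2_stack(fmri$frames, fmri$n_regions)
  exceed <- matrix(0L, nrow(r_obs), ncol(r_obs))
  for (p in seq_len(n_perm)) {
    surr <- permute_from_fft2(pre)
    r_null <- tcrossprod(normalize_rows(surr), eeg_n)
    r_null[is.na(r_null)] <- 0
    exceed <- exceed + (r_null >= r_obs)
  }
  pmat <- (1 + exceed) / (n_perm + 1)
  if (positive_only) pmat[r_obs <= 0] <- 1
  list(r = r_obs, p = pmat)
}

#' Benjamini-Hochberg binarization of a CRP p-value matrix
#'
#' Step-up FDR correction applied jointly over all `S_f x S_e` entries of
#' one band's CRP (the correction is for the number of all pairs of
#' timepoints).
#'
#' @param p_values Matrix of empirical p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical matrix of significant entries.
#' @export
fdr_binarize <- function(p_values, q = 0.05) {
  stopifnot(all(p_values > 0), all(p_values <= 1), q > 0, q < 1)
  adj <- stats::p.adjust(as.vector(p_values), method = "BH")
  matrix(adj <= q, nrow(p_values), ncol(p_values))
}

#' Overlay band-specific binary CRPs into a multi-frequency CRP
#'
#' @param layers Named list of logical matrices (one per band, equal shape).
#' @return A `multifreq_crp` object: the per-band layers plus their
#'   entrywise union.
#' @export
overlay_bands <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("band layers must share the same shape", call. = FALSE)
  }
  structure(list(layers = layers, union = Reduce(`|`, layers),
                 bands = names(layers)),
            class = "multifreq_crp")
}

#' @export
print.multifreq_crp <- function(x, ...) {
  cat(sprintf("<multifreq_crp> %d x %d, %d band layer(s), union density %.3f\n",
              nrow(x$union), ncol(x$union), length(x$layers), mean(x$union)))
  invisible(x)
}

#' Build the full CRP stack for one subject
#'
#' Runs [entrywise_null_test()] and [fdr_binarize()] for every band-specific
#' fast-modality edge series against one (already shifted and aligned)
#' slow-modality series, and overlays the binary layers.
#'
#' @param fmri Slow-modality [edge_frame_series()].
#' @param eeg_by_band Named list of fast-modality [edge_frame_series()].
#' @param config [analysis_config()] settings.
#' @param seed Optional integer seed.
#' @return A `crp_stack` object: per-band `r`, `p`, `binary`, the
#'   multi-frequency union, and the settings used.
#' @export
crp_stack <- function(fmri, eeg_by_band, config = analysis_config(), seed = NULL) {
  stopifnot(is.list(eeg_by_band), length(eeg_by_band) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  per_band <- lapply(eeg_by_band, function(eeg) {
    al <- align_frames(fmri, eeg)
    res <- entrywise_null_test(al$a, al$b, n_perm = config$n_perm)
    res$binary <- fdr_binarize(res$p, config$q)
    res
  })
  layers <- lapply(per_band, `[[`, "binary")
  structure(list(bands = per_band,
                 mfcrp = overlay_bands(layers),
                 q = config$q, n_perm = config$n_perm),
            class = "crp_stack")
}

#' @export
print.crp_stack <- function(x, ...) {
  cat(sprintf("<crp_stack> %d band(s), q = %g, n_perm = %d, union density %.3f\n",
              length(x$bands), x$q, x$n_perm, mean(x$mfcrp$union)))
  invisible(x)
}
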