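# Recurrent connectome states: pooled-frame K-means clustering per
# timescale and a dissociability test of the resulting states against
# temporal phase-permutation surrogates that preserve the static connectome
# but destroy frame-wise dynamics.

#' Pool connectome frames across subjects
#'
#' @param series_list List of [edge_frame_series()] objects sharing an edge
#'   set (one per subject).
#' @return List with `frames` (row-stacked matrix) and `subject` (integer
#'   index per row).
#' @export
pool_frames <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  r0 <- series_list[[1]]$n_regions
  for (s in series_list) {
    if (!inherits(s, "edge_frame_series") || s$n_regions != r0) {
      stop("all series must share the same edge set", call. = FALSE)
    }
  }
  frames <- do.call(rbind, lapply(series_list, `[[`, "frames"))
  subject <- rep(seq_along(series_list),
                 vapply(series_list, function(s) nrow(s$frames), integer(1)))
  list(frames = frames, subject = subject)
}

#' K-means connectome states
#'
#' Euclidean K-means on pooled connectome frames with 20 random restarts
#' (best within-cluster sum of squares kept).
#'
#' @param frames Numeric frames x edges matrix.
#' @param k Number of states (typically 5, replicated with 7).
#' @param seed Optional integer seed.
#' @param nstart Number of restarts (default 20).
#' @return A `state_clustering` object: `centroids` (k x E), `labels`,
#'   `k`, `inertia`.
#' @export
kmeans_states <- function(frames, k, seed = NULL, nstart = 20L) {
  frames <- as.matrix(frames)
  if (k > nrow(frames)) stop("more states requested than frames", call. = FALSE)
  if (nrow(frames) < 10L * k) {
    warning(sprintf("only %d frames for k = %d states; labels may be unstable",
                    nrow(frames), k))
  }
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(frames, centers = k, nstart = nstart, iter.max = 100L)
  structure(list(centroids = km$centers, labels = km$cluster, k = as.integer(k),
                 inertia = km$tot.withinss),
            class = "state_clustering")
}

#' Frame-by-frame proximity matrix
#'
#' Pairwise Pearson similarity between connectome frames, rows and columns
#' sorted by cluster label when labels are supplied (the sorting makes the
#' within-state block structure visible; the dissociability statistic is
#' invariant to it).
#'
#' @param frames Numeric frames x edges matrix.
#' @param labels Optional cluster labels used to sort rows/columns.
#' @return List with `proximity` (symmetric, unit diagonal) and `order`.
#' @export
proximity_matrix <- function(frames, labels = NULL) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  sds <- apply(frames, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance frame(s): %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  ord <- if (is.null(labels)) seq_len(nrow(frames)) else order(labels)
  prox <- stats::cor(t(frames[ord, , drop = FALSE]))
  list(proximity = prox, order = ord)
}

#' Dissociability of clustered states
#'
#' Pearson correlation between the off-diagonal entries of the frame
#' proximity matrix and the ideal binary within-cluster indicator (1 for
#' frame pairs sharing a cluster label, 0 otherwise). Values near 1 indicate
#' cleanly separated states; label-independent proximity gives values near 0.
#'
#' @param proximity Symmetric frame-similarity matrix.
#' @param labels Cluster label per frame, in the row order of `proximity`.
#' @return Scalar dissociability.
#' @export
dissociability <- function(proximity, labels) {
  stopifnot(is.matrix(proximity), nrow(proximity) == ncol(proximity),
            length(labels) == nrow(proximity))
  if (length(unique(labels)) < 2L) {
    warning("single cluster: dissociability undefined")
    return(NA_real_)
  }
  off <- upper.tri(proximity)
  indicator <- outer(labels, labels, `==`)
  stats::cor(proximity[off], as.numeric(indicator[off]))
}

#' Dissociability z-score against phase-permutation surrogates
#'
#' Clusters the pooled frames, computes the real dissociability, then repeats
#' the whole procedure (surrogate generation per subject via
#' [temporal_phase_permute_edges()], re-pooling, re-clustering with fresh
#' restarts, proximity, dissociability) for `n_surrogates` surrogate data
#' sets, and returns the z-score of the real value against the surrogate
#' distribution.
#'
#' @param series_list Per-subject list of [edge_frame_series()].
#' @param k Number of states.
#' @param n_surrogates Number of surrogate data sets (default 50, >= 20).
#' @param seed Optional integer seed.
#' @param nstart K-means restarts (default 20).
#' @return List with `z`, `real`, `null_values`, `clustering`.
#' @export
dissociability_zscore <- function(series_list, k, n_surrogates = 50L,
                                  seed = NULL, nstart = 20L) {
  stopifnot(n_surrogates >= 20L)
  if (!is.null(seed)) set.seed(seed)
  pooled <- pool_frames(series_list)
  cl <- kmeans_states(pooled$frames, k, nstart = nstart)
  real <- dissociability(proximity_matrix(pooled$frames)$proximity, cl$labels)
  nulls <- vapply(seq_len(n_surrogates), function(s) {
    surr <- lapply(series_list, temporal_phase_permute_edges)
    sp <- pool_frames(surr)
    scl <- kmeans_states(sp$frames, k, nstart = nstart)
    dissociability(proximity_matrix(sp$frames)$proximity, scl$labels)
  }, numeric(1))
  null_sd <- stats::sd(nulls)
  if (null_sd == 0) stop("degenerate surrogate distribution (zero SD)", call. = FALSE)
  list(z = (real - mean(nulls)) / null_sd, real = real, null_values = nulls,
       clustering = cl)
}
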