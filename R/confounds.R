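# Nuisance checks: does the cross-modal similarity timecourse track overall
# FC strength, head motion (framewise displacement), static-connectome
# prominence, or artifact epochs? Plus the within-network (ICN) strength
# illustration.

#' Synchronous cross-modal similarity timecourse
#'
#' The main-diagonal entries of a (lag-corrected, square-aligned) CRP: the
#' spatial similarity of the two modalities' connectome frames at
#' synchronous timepoints.
#'
#' @param r_values Square numeric CRP correlation matrix.
#' @return Numeric vector of length `S`.
#' @export
similarity_timecourse <- function(r_values) {
  stopifnot(is.matrix(r_values))
  if (nrow(r_values) != ncol(r_values)) {
    stop("CRP must be square-aligned (apply the hemodynamic shift first)", call. = FALSE)
  }
  diag(r_values)
}

#' Overall FC-strength timecourse
#'
#' Per frame, the root sum of squares of the edge values over all
#' connections.
#'
#' @param frames An [edge_frame_series()].
#' @return Numeric vector, one value per frame.
#' @export
fc_strength_timecourse <- function(frames) {
  stopifnot(inherits(frames, "edge_frame_series"))
  sqrt(rowSums(frames$frames^2))
}

#' Framewise displacement from 6-parameter motion estimates
#'
#' `FD(t) = sum |d translation| + radius * sum |d rotation|`, with rotations
#' converted to millimetres of arc on a sphere of the given radius; the
#' first frame is 0 by convention.
#'
#' @param motion Numeric matrix or data.frame with exactly 6 columns: three
#'   translations (mm) then three rotations (radians).
#' @param radius_mm Head-radius used to convert rotations to mm (default 50).
#' @return Numeric FD vector, one value per frame.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion table must have 6 columns (3 translations, 3 rotations)", call. = FALSE)
  }
  d <- abs(apply(motion, 2, function(col) c(0, diff(col))))
  rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Static-connectome prominence timecourse
#'
#' Per frame, the Pearson correlation (across edges) between the frame's
#' connectome configuration and the series' static (time-averaged)
#' connectome: how strongly the static organization is expressed at each
#' timepoint.
#'
#' @param frames An [edge_frame_series()] with at least 8 edges.
#' @return Numeric vector, one value per frame.
#' @export
static_prominence_timecourse <- function(frames) {
  stopifnot(inherits(frames, "edge_frame_series"))
  if (ncol(frames$frames) < 8L) stop("need at least 8 edges", call. = FALSE)
  static <- static_fc(frames)
  if (stats::sd(static) == 0) stop("zero-variance static connectome", call. = FALSE)
  as.vector(stats::cor(t(frames$frames), static))
}

#' Correlation of two timecourses with a phase-permutation null
#'
#' Observed Pearson correlation of `x` and `y`, with a two-sided empirical
#' p-value against `n_perm` Fourier phase-randomized versions of `x` (the
#' cross-modal similarity timecourse is the one randomized in the nuisance
#' analyses).
#'
#' @param x,y Equal-length numeric vectors (length >= 16).
#' @param n_perm Number of surrogates (default 100).
#' @param seed Optional integer seed.
#' @return List with `r`, `p`, `null_r`.
#' @export
timecourse_null_correlation <- function(x, y, n_perm = 100L, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 16L)
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, y)
  n <- length(x)
  null_r <- vapply(seq_len(n_perm), function(p) {
    phi <- hermitian_phases_1d(n)
    xs <- Re(stats::fft(stats::fft(x) * exp(1i * phi), inverse = TRUE)) / n
    stats::cor(xs, y)
  }, numeric(1))
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p = p, null_r = null_r)
}

#' Overlap of artifact epochs with significant cross-modal similarity
#'
#' Jaccard overlap between the binarized (significance-thresholded)
#' cross-modal similarity timecourse and a boolean artifact-interval mask,
#' with a one-tailed empirical p-value against circularly shifted versions
#' of the similarity timecourse (random shifts between 1 and T - 1, shift 0
#' excluded, drawn without replacement when possible).
#'
#' @param sim_binary Logical per-TR significance of the synchronous CRP entry.
#' @param artifact_mask Logical per-TR artifact indicator, same length.
#' @param n_shifts Number of null shifts (default 100).
#' @param seed Optional integer seed.
#' @return List with `jaccard`, `p`, `null_jaccard`.
#' @export
artifact_overlap_test <- function(sim_binary, artifact_mask, n_shifts = 100L,
                                  seed = NULL) {
  stopifnot(is.logical(sim_binary), is.logical(artifact_mask),
            length(sim_binary) == length(artifact_mask))
  if (!any(artifact_mask)) {
    warning("empty artifact mask: overlap undefined")
    return(list(jaccard = NA_real_, p = NA_real_, null_jaccard = numeric(0)))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(sim_binary)
  obs <- suppressWarnings(jaccard(sim_binary, artifact_mask))
  pool <- seq_len(n - 1L)
  shifts <- if (n_shifts < length(pool)) sample(pool, n_shifts) else
    sample(pool, n_shifts, replace = TRUE)
  null_j <- vapply(shifts, function(s) {
    rolled <- c(sim_binary[(n - s + 1L):n], sim_binary[seq_len(n - s)])
    suppressWarnings(jaccard(rolled, artifact_mask))
  }, numeric(1))
  p <- (1 + sum(null_j >= obs, na.rm = TRUE)) / (sum(is.finite(null_j)) + 1)
  list(jaccard = obs, p = p, null_jaccard = null_j)
}

#' Within-network connectivity-strength timecourse
#'
#' Mean frame-wise FC over all region pairs inside one intrinsic
#' connectivity network, z-scored across frames, with a boolean emergence
#' mask at `z > 2`.
#'
#' @param frames An [edge_frame_series()].
#' @param membership Character vector giving each region's network, in
#'   region order (length `n_regions`), or a two-column data.frame
#'   (region, network) in region order.
#' @param network Name of the network to summarize.
#' @return List with `z` (per-frame z-scored strength), `active` (`z > 2`),
#'   `edges` (edge indices used).
#' @export
network_strength_timecourse <- function(frames, membership, network) {
  stopifnot(inherits(frames, "edge_frame_series"))
  if (is.data.frame(membership)) membership <- as.character(membership[[2]])
  stopifnot(length(membership) == frames$n_regions)
  regions <- which(membership == network)
  if (length(regions) < 2L) {
    stop(sprintf("network '%s' has fewer than 2 regions", network), call. = FALSE)
  }
  ei <- edge_index(frames$n_regions)
  sel <- which(ei$i %in% regions & ei$j %in% regions)
  strength <- rowMeans(frames$frames[, sel, drop = FALSE])
  if (stats::sd(strength) == 0) {
    stop("constant network strength timecourse: z-score undefined", call. = FALSE)
  }
  z <- as.vector(scale(strength))
  list(z = z, active = z > 2, edges = sel)
}
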