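#' Canonical electrophysiological frequency bands
#'
#' The five canonical bands used throughout: delta (1-4 Hz), theta (5-7 Hz),
#' alpha (8-13 Hz), beta (14-30 Hz) and gamma (31-60 Hz).
#'
#' @param names Optional character vector restricting which bands to return.
#' @return A named list of band specs, each a list with `name`, `low`, `high`.
#' @export
canonical_bands <- function(names = c("delta", "theta", "alpha", "beta", "gamma")) {
  all <- list(
    delta = band_spec("delta", 1, 4),
    theta = band_spec("theta", 5, 7),
    alpha = band_spec("alpha", 8, 13),
    beta  = band_spec("beta", 14, 30),
    gamma = band_spec("gamma", 31, 60)
  )
  names <- match.arg(names, choices = names(all), several.ok = TRUE)
  all[names]
}

#' Construct a frequency band specification
#'
#' @param name Band label (one of delta, theta, alpha, beta, gamma).
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A `band_spec` object.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (!(low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Construct a region-by-time signal set
#'
#' Container for one modality's multivariate recording: a numeric
#' region x time matrix together with its sampling rate and modality tag.
#'
#' @param values Numeric matrix, regions in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param modality `"fast"` (electrophysiology-like) or `"slow"` (BOLD-like).
#' @param region_labels Optional unique region names; defaults to `R1..Rn`.
#' @param band Optional [band_spec()] describing the band content of `values`.
#' @return A `region_signal_set` object.
#' @export
region_signal_set <- function(values, fs, modality = c("fast", "slow"),
                              region_labels = NULL, band = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("signal values must be a finite numeric matrix", call. = FALSE)
  }
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(region_labels)) {
    region_labels <- paste0("R", seq_len(nrow(values)))
  }
  if (anyDuplicated(region_labels)) {
    stop("region labels must be unique", call. = FALSE)
  }
  stopifnot(length(region_labels) == nrow(values))
  if (!is.null(band)) stopifnot(inherits(band, "band_spec"))
  dimnames(values) <- NULL
  rownames(values) <- region_labels
  structure(list(values = values, fs = fs, modality = modality,
                 region_labels = region_labels, band = band),
            class = "region_signal_set")
}

#' @export
print.region_signal_set <- function(x, ...) {
  cat(sprintf("<region_signal_set> %d regions x %d samples, fs = %g Hz, modality = %s%s\n",
              nrow(x$values), ncol(x$values), x$fs, x$modality,
              if (is.null(x$band)) "" else paste0(", band = ", x$band$name)))
  invisible(x)
}

#' Row-major upper-triangle edge index table
#'
#' Fixed edge ordering used by every frame-wise connectivity container:
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param n_regions Number of regions R.
#' @return A data.frame with integer columns `i`, `j` (i < j), one row per edge.
#' @export
edge_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions),
              use.names = FALSE)
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Extract the row-major upper triangle of a symmetric matrix as an edge vector
#' @param mat Square matrix.
#' @return Numeric vector of length R(R-1)/2 in [edge_index()] order.
#' @export
upper_tri_vec <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  t(mat)[lower.tri(mat)]
}

#' Re-assemble an edge vector into a symmetric matrix
#' @param edges Edge vector in [edge_index()] order.
#' @param n_regions Number of regions R.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return Symmetric R x R matrix.
#' @export
edges_to_matrix <- function(edges, n_regions, diag_value = 0) {
  stopifnot(length(edges) == n_regions * (n_regions - 1L) / 2L)
  mt <- matrix(0, n_regions, n_regions)
  mt[lower.tri(mt)] <- edges
  m <- t(mt) + mt
  diag(m) <- diag_value
  m
}

#' Construct a frame-wise edge series
#'
#' A T x E matrix of connectome frames: one row per repetition-time (TR)
#' frame, one column per upper-triangle edge in [edge_index()] order.
#'
#' @param frames Numeric T x E matrix.
#' @param n_regions Number of regions R consistent with `E = R(R-1)/2`.
#' @param tr Repetition time (frame step) in seconds.
#' @param frame_index Integer frame indices on the TR grid (default `1:T`).
#' @param coupling One of `"amp"`, `"phase"`, `"bold"`.
#' @param band Optional [band_spec()].
#' @param shifted Logical; has the hemodynamic shift been applied?
#' @return An `edge_frame_series` object.
#' @export
edge_frame_series <- function(frames, n_regions, tr,
                              frame_index = seq_len(nrow(frames)),
                              coupling = c("bold", "amp", "phase"),
                              band = NULL, shifted = FALSE) {
  coupling <- match.arg(coupling)
  frames <- as.matrix(frames)
  e_expect <- n_regions * (n_regions - 1L) / 2L
  if (ncol(frames) != e_expect) {
    stop(sprintf("frames has %d columns but R = %d implies %d edges",
                 ncol(frames), n_regions, e_expect), call. = FALSE)
  }
  if (!all(is.finite(frames))) stop("non-finite frame values", call. = FALSE)
  if (coupling == "phase" && (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)) {
    stop("phase-coupling values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(frame_index) == nrow(frames), tr > 0)
  dimnames(frames) <- NULL
  structure(list(frames = frames, n_regions = as.integer(n_regions), tr = tr,
                 frame_index = as.integer(frame_index), coupling = coupling,
                 band = band, shifted = isTRUE(shifted)),
            class = "edge_frame_series")
}

#' @export
print.edge_frame_series <- function(x, ...) {
  cat(sprintf("<edge_frame_series> %d frames x %d edges (R = %d), tr = %g s, coupling = %s%s%s\n",
              nrow(x$frames), ncol(x$frames), x$n_regions, x$tr, x$coupling,
              if (is.null(x$band)) "" else paste0(", band = ", x$band$name),
              if (x$shifted) ", shifted" else ""))
  invisible(x)
}

#' Restrict two edge series to their common TR frames
#'
#' Frames are matched on `frame_index`, so series that dropped different
#' boundary frames (or were shifted) are paired correctly.
#'
#' @param a,b `edge_frame_series` objects over the same edge set.
#' @return List with elements `a` and `b`, both restricted to shared frames.
#' @export
align_frames <- function(a, b) {
  stopifnot(inherits(a, "edge_frame_series"), inherits(b, "edge_frame_series"))
  if (a$n_regions != b$n_regions) {
    stop("edge sets differ: series have different region counts", call. = FALSE)
  }
  common <- intersect(a$frame_index, b$frame_index)
  if (length(common) == 0L) stop("no overlapping frames", call. = FALSE)
  sel_a <- match(common, a$frame_index)
  sel_b <- match(common, b$frame_index)
  a$frames <- a$frames[sel_a, , drop = FALSE]; a$frame_index <- common
  b$frames <- b$frames[sel_b, , drop = FALSE]; b$frame_index <- common
  list(a = a, b = b)
}

# population z-score (divide by T, not T-1) so that the frame-wise
# self-product identity holds with mean exactly 1
zscore_pop <- function(x) {
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  if (sdv == 0) stop("zero-variance signal cannot be z-scored", call. = FALSE)
  (x - mu) / sdv
}
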