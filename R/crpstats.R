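# Convergence statistics on binary CRPs: on-/off-diagonal ratio across
# diagonal shifts with CRP-randomization nulls, subject-level non-parametric
# tests, group-level one-tailed JZS Bayes factors, inter-band Jaccard
# overlap, static cross-modal similarity, and connection-level temporal
# convergence.

#' On-/off-diagonal ratio of a binary CRP
#'
#' Rate of significant entries on the `k`-shifted main diagonal (entries
#' `(a, a + k)`) divided by the rate among all other entries. A ratio near 1
#' indicates that cross-modal convergence is as likely at asynchronous as at
#' synchronous timepoint pairs; a ratio clearly above 1 indicates synchronous
#' (temporally convergent) epochs. Entries cut off the matrix by the shift
#' simply do not contribute. An empty off-diagonal rate yields `NA` with a
#' warning rather than an infinite ratio.
#'
#' @param binary Logical matrix (rows: slow-modality frames, columns:
#'   fast-modality frames).
#' @param shift Integer diagonal shift `k` in TR units, `|k| < min(dim)`.
#' @return The ratio (numeric scalar, possibly `NA`).
#' @export
on_off_ratio <- function(binary, shift = 0L) {
  stopifnot(is.matrix(binary), is.logical(binary))
  s <- as.integer(shift)
  if (abs(s) >= min(dim(binary))) stop("|shift| must be smaller than the CRP size", call. = FALSE)
  a <- seq_len(nrow(binary))
  b <- a + s
  ok <- b >= 1L & b <= ncol(binary)
  diag_idx <- cbind(a[ok], b[ok])
  on_rate <- mean(binary[diag_idx])
  n_total <- length(binary)
  n_on <- nrow(diag_idx)
  off_rate <- (sum(binary) - sum(binary[diag_idx])) / (n_total - n_on)
  if (off_rate == 0) {
    warning("no significant off-diagonal entries: ratio undefined")
    return(NA_real_)
  }
  on_rate / off_rate
}

#' On-/off-diagonal ratio profile across diagonal shifts
#'
#' Computes the ratio of [on_off_ratio()] for every shift (default -5..+5 TR)
#' and, for each shift, an empirical one-tailed p-value against ratios of
#' `n_null_crp` phase-randomized, density-matched surrogate CRPs
#' ([phase_randomize_crp()]).
#'
#' @param mfcrp A `multifreq_crp` (the union layer is used) or a single
#'   logical matrix.
#' @param config [analysis_config()] settings (`shifts`, `n_null_crp`).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `shift`, `ratio`, `null_mean`,
#'   `null_sd`, `p`, plus attribute `null_ratios` (shift x surrogate matrix).
#' @export
diagonal_profile <- function(mfcrp, config = analysis_config(), seed = NULL) {
  binary <- if (inherits(mfcrp, "multifreq_crp")) mfcrp$union else mfcrp
  stopifnot(is.matrix(binary), is.logical(binary))
  if (min(dim(binary)) <= max(abs(config$shifts)) + 1L) {
    stop("CRP too small for the requested diagonal shifts", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  shifts <- config$shifts
  obs <- vapply(shifts, function(k) suppressWarnings(on_off_ratio(binary, k)),
                numeric(1))
  nulls <- matrix(NA_real_, length(shifts), config$n_null_crp)
  for (s in seq_len(config$n_null_crp)) {
    surr <- phase_randomize_crp(mfcrp)
    surr_bin <- if (inherits(surr, "multifreq_crp")) surr$union else surr
    nulls[, s] <- vapply(shifts, function(k) {
      suppressWarnings(on_off_ratio(surr_bin, k))
    }, numeric(1))
  }
  p <- vapply(seq_along(shifts), function(i) {
    ok <- is.finite(nulls[i, ])
    if (!is.finite(obs[i]) || sum(ok) < 20L) return(NA_real_)
    subject_nonparametric_p(obs[i], nulls[i, ok])
  }, numeric(1))
  out <- data.frame(shift = shifts, ratio = obs,
                    null_mean = rowMeans(nulls, na.rm = TRUE),
                    null_sd = apply(nulls, 1, stats::sd, na.rm = TRUE),
                    p = p)
  attr(out, "null_ratios") <- nulls
  out
}

#' Subject-level non-parametric test of an observed ratio against its null
#'
#' One-tailed empirical p-value `(1 + #\{null >= observed\}) / (n_null + 1)`.
#'
#' @param observed Observed scalar statistic.
#' @param null_values Numeric vector of >= 20 null statistics.
#' @return Empirical p-value.
#' @export
subject_nonparametric_p <- function(observed, null_values) {
  null_values <- null_values[is.finite(null_values)]
  if (length(null_values) < 20L) stop("need at least 20 null values", call. = FALSE)
  if (!is.finite(observed)) return(NA_real_)
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}

#' One-tailed JZS Bayes factor for a paired comparison (BF01)
#'
#' Bayesian paired t-test with a Cauchy prior (scale 0.707 by default) on the
#' standardized effect size, truncated to the one-sided alternative
#' H1: observed > null (temporal convergence, i.e. on-/off-diagonal ratio
#' above its null). Returns BF01, the evidence in favor of H0 (no
#' convergence) over H1. Computed by numerical integration of the
#' non-central t likelihood over the truncated Cauchy prior.
#'
#' @param observed Per-subject observed values.
#' @param null_means Per-subject null means (paired with `observed`).
#' @param prior_scale Cauchy prior scale (default 0.707).
#' @return List with `bf01`, `bf10`, `t`, `df`.
#' @export
bayes_paired_ttest_bf01 <- function(observed, null_means, prior_scale = 0.707) {
  stopifnot(length(observed) == length(null_means), length(observed) >= 3L)
  d <- observed - null_means
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of paired differences: test degenerate", call. = FALSE)
  tval <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  # marginal likelihood under H1: integrate t density with non-centrality
  # delta * sqrt(n) over the half-Cauchy prior on delta > 0
  integrand <- function(delta) {
    stats::dt(tval, df = df, ncp = delta * sqrt(n)) *
      2 * stats::dcauchy(delta, location = 0, scale = prior_scale)
  }
  m1 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                         stop.on.error = FALSE)$value
  m0 <- stats::dt(tval, df = df)
  bf10 <- m1 / m0
  list(bf01 = 1 / bf10, bf10 = bf10, t = tval, df = df)
}

#' Jaccard overlap of two binary matrices
#'
#' `sum(A & B) / sum(A | B)`; the overlap of significant epochs between two
#' band-specific CRPs. Undefined (NA, with a warning) when both are empty.
#'
#' @param a,b Logical matrices or vectors of identical shape.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), length(a) == length(b))
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warning("both masks empty: Jaccard undefined")
    return(NA_real_)
  }
  sum(a & b) / union_n
}

#' Pairwise inter-band Jaccard matrix of a multi-frequency CRP
#'
#' @param mfcrp A `multifreq_crp` object.
#' @return Symmetric matrix of Jaccard indices between band layers.
#' @export
band_jaccard_matrix <- function(mfcrp) {
  stopifnot(inherits(mfcrp, "multifreq_crp"))
  b <- length(mfcrp$layers)
  out <- matrix(NA_real_, b, b, dimnames = list(mfcrp$bands, mfcrp$bands))
  for (i in seq_len(b)) {
    for (j in seq_len(b)) {
      out[i, j] <- if (i == j) 1 else
        suppressWarnings(jaccard(mfcrp$layers[[i]], mfcrp$layers[[j]]))
    }
  }
  out
}

#' Static cross-modal spatial similarity
#'
#' Pearson correlation across edges between the time-averaged (static)
#' connectomes of the two modalities.
#'
#' @param static_fmri,static_eeg Edge vectors in the shared edge order.
#' @return Correlation coefficient.
#' @export
static_crossmodal_similarity <- function(static_fmri, static_eeg) {
  if (length(static_fmri) != length(static_eeg)) {
    stop("edge vectors differ in length: edge-order mismatch", call. = FALSE)
  }
  stats::cor(static_fmri, static_eeg)
}

#' Connection-level temporal convergence
#'
#' Per-edge Pearson correlation over time between the slow-modality edge
#' series and a (typically HRF-convolved) fast-modality edge series on
#' aligned frames, with one-tailed significance from temporal phase
#' permutation of the fast-modality series and BH-FDR across edges.
#'
#' @param fmri,eeg_hrf Aligned [edge_frame_series()] objects (same frames).
#' @param n_perm Number of temporal phase permutations (default 100).
#' @param q FDR level (default 0.05).
#' @param seed Optional integer seed.
#' @return data.frame with columns `edge`, `r`, `p`, `significant`.
#' @export
edge_temporal_convergence <- function(fmri, eeg_hrf, n_perm = 100L, q = 0.05,
                                      seed = NULL) {
  al <- align_frames(fmri, eeg_hrf)
  x <- al$a$frames; y <- al$b$frames
  if (nrow(x) < 8L) stop("need at least 8 aligned frames", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r_obs <- vapply(seq_len(ncol(x)), function(e) stats::cor(x[, e], y[, e]), numeric(1))
  exceed <- integer(ncol(x))
  for (p in seq_len(n_perm)) {
    surr <- temporal_phase_permute_edges(al$b)
    r_null <- vapply(seq_len(ncol(x)), function(e) stats::cor(x[, e], surr$frames[, e]),
                     numeric(1))
    exceed <- exceed + (r_null >= r_obs)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  sig <- stats::p.adjust(pvals, method = "BH") <= q
  data.frame(edge = seq_len(ncol(x)), r = r_obs, p = pvals, significant = sig)
}
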