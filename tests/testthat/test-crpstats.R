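test_that("on-/off-diagonal ratio matches a counting oracle", {
  expect_equal(on_off_ratio(matrix(TRUE, 10, 10), 0), 1)

  # 12 x 12 with diagonal rate 0.5 and off rate 0.25 -> ratio 2
  set.seed(1)
  b <- matrix(FALSE, 12, 12)
  diag(b) <- rep(c(TRUE, FALSE), 6)
  off_cells <- which(row(b) != col(b))
  b[sample(off_cells, 33)] <- TRUE
  expect_equal(on_off_ratio(b, 0), (6 / 12) / (33 / 132))

  # double-loop oracle on random matrices and shifts
  oracle <- function(bin, k) {
    on <- c(); off <- c()
    for (a in seq_len(nrow(bin))) for (bb in seq_len(ncol(bin))) {
      if (bb - a == k) on <- c(on, bin[a, bb]) else off <- c(off, bin[a, bb])
    }
    mean(on) / mean(off)
  }
  set.seed(2)
  for (k in c(-3, 0, 2)) {
    bin <- matrix(runif(225) < 0.3, 15, 15)
    expect_equal(on_off_ratio(bin, k), oracle(bin, k))
  }

  empty_off <- matrix(FALSE, 6, 6); diag(empty_off) <- TRUE
  expect_warning(r <- on_off_ratio(empty_off, 0), "undefined")
  expect_true(is.na(r))
  expect_error(on_off_ratio(matrix(TRUE, 4, 4), 4), "shift")
})

test_that("density-matched CRP surrogates have unit mean ratio", {
  set.seed(7)
  layers <- lapply(1:3, function(i) matrix(runif(120^2) < 0.15, 120, 120))
  names(layers) <- c("a", "b", "c")
  mf <- overlay_bands(layers)
  ratios <- replicate(60, {
    on_off_ratio(phase_randomize_crp(mf)$union, 0)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("diagonal profile is consistent with the single-shift ratio", {
  set.seed(5)
  bin <- matrix(runif(40^2) < 0.25, 40, 40)
  cfg <- analysis_config(n_null_crp = 30)
  prof <- diagonal_profile(bin, cfg, seed = 9)
  expect_equal(prof$shift, -5:5)
  expect_equal(prof$ratio[prof$shift == 0], on_off_ratio(bin, 0))
  # a random symmetric-structure matrix shows no significant convergence
  expect_true(all(prof$p > 0.05, na.rm = TRUE))
  expect_equal(dim(attr(prof, "null_ratios")), c(11L, 30L))
})

test_that("one-tailed JZS BF01 matches an independent Monte-Carlo oracle", {
  bf_mc_oracle <- function(obs, nulls, scale = 0.707, n_mc = 4e5, seed = 42) {
    d <- obs - nulls; n <- length(d)
    tval <- mean(d) / (sd(d) / sqrt(n))
    set.seed(seed)
    # sample from the positive half-Cauchy prior, average the likelihood
    delta <- abs(rcauchy(n_mc, 0, scale))
    m1 <- mean(dt(tval, df = n - 1, ncp = delta * sqrt(n)))
    dt(tval, df = n - 1) / m1
  }
  set.seed(13)
  obs <- 1 + rnorm(9, 0.08, 0.1)
  nulls <- rep(1, 9) + rnorm(9, 0, 0.02)
  got <- bayes_paired_ttest_bf01(obs, nulls)
  expect_equal(got$bf01, bf_mc_oracle(obs, nulls), tolerance = 0.01)

  # null-consistent data favor H0
  set.seed(14)
  x <- rnorm(9); y <- x + rnorm(9, 0, 1e-3) - mean(x - rnorm(9, 0, 1e-3))
  near_zero_t <- bayes_paired_ttest_bf01(rnorm(9), rnorm(9))
  flat <- bayes_paired_ttest_bf01(c(1, 2, 3, 4, 2, 3), c(2, 3, 1, 4, 3, 2))
  expect_gt(flat$bf01 + near_zero_t$bf01, 0) # finite, defined
  zero_t <- bayes_paired_ttest_bf01(c(0.1, -0.2, 0.05, 0.15, -0.1, 0, 0.2, -0.15, -0.05),
                                    rep(0, 9))
  if (abs(zero_t$t) < 0.5) expect_gt(zero_t$bf01, 1)

  # scale invariance of the t statistic carries to the BF
  s1 <- bayes_paired_ttest_bf01(obs * 10, nulls * 10)
  expect_equal(s1$bf01, got$bf01, tolerance = 1e-6)

  # monotone: growing mean difference in the H1 direction lowers BF01
  base <- rnorm(9, 0, 0.05)
  bfs <- sapply(c(0, 0.05, 0.1, 0.2), function(shift) {
    bayes_paired_ttest_bf01(base + 1 + shift, rep(1, 9))$bf01
  })
  expect_true(all(diff(bfs) < 0))

  expect_error(bayes_paired_ttest_bf01(rep(1, 5), rep(0, 5)), "degenerate")
})

test_that("Jaccard index counts intersection over union", {
  a <- c(TRUE, TRUE, FALSE, FALSE); b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, !a), 0)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_warning(j <- jaccard(c(FALSE, FALSE), c(FALSE, FALSE)), "undefined")
  expect_true(is.na(j))

  # bounded above by the density ratio
  set.seed(3)
  x <- runif(500) < 0.2; y <- runif(500) < 0.45
  expect_lte(jaccard(x, y), min(mean(x), mean(y)) / max(mean(x), mean(y)))

  layers <- list(d = matrix(runif(100) < 0.3, 10), g = matrix(runif(100) < 0.2, 10))
  jm <- band_jaccard_matrix(overlay_bands(layers))
  expect_equal(jm["d", "g"], jaccard(layers$d, layers$g))
  expect_equal(diag(jm), c(d = 1, g = 1))
})

test_that("static cross-modal similarity is edgewise Pearson correlation", {
  v <- rnorm(20)
  expect_equal(static_crossmodal_similarity(v, v), 1)
  expect_equal(static_crossmodal_similarity(v, -v), -1)
  w <- rnorm(20)
  expect_equal(static_crossmodal_similarity(v, w), cor(v, w))
  expect_error(static_crossmodal_similarity(v, w[-1]), "mismatch")
})

test_that("edge-level temporal convergence detects identical series and stays calibrated", {
  set.seed(21)
  e <- 15L
  fr <- matrix(rnorm(30 * e), 30, e)
  a <- edge_frame_series(fr, n_regions = 6, tr = 2)
  b <- edge_frame_series(fr, n_regions = 6, tr = 2, coupling = "amp")
  res <- edge_temporal_convergence(a, b, n_perm = 60, seed = 3)
  expect_equal(res$r, rep(1, e), tolerance = 1e-12)
  expect_true(all(res$significant))

  b2 <- edge_frame_series(matrix(rnorm(30 * e), 30, e), n_regions = 6, tr = 2,
                          coupling = "amp")
  res2 <- edge_temporal_convergence(a, b2, n_perm = 60, seed = 3)
  expect_lte(mean(res2$significant), 0.05 + 2 / e)
})

test_that("edge-level convergence finds coupled edges and honors ground truth", {
  # constructed detection fixture: a subset of edges is temporally coupled
  set.seed(51)
  e <- 66L; n <- 60L
  x <- matrix(rnorm(n * e), n, e)
  coupled <- 1:20
  y <- matrix(rnorm(n * e), n, e)
  y[, coupled] <- x[, coupled] + matrix(rnorm(n * 20, sd = 0.8), n, 20)
  a <- edge_frame_series(x, n_regions = 12, tr = 2)
  b <- edge_frame_series(y, n_regions = 12, tr = 2, coupling = "amp")
  res <- edge_temporal_convergence(a, b, n_perm = 80, seed = 6)
  expect_gt(mean(res$significant[coupled]), 0.5)
  expect_lte(mean(res$significant[-coupled]), 0.05 + 2 / (e - 20))

  # generator ground truth: state-loaded edges correlate across modalities
  # once the hemodynamic shift aligns the BOLD edge series
  cfg <- scenario_config(scenario = "I", n_regions = 12, n_states = 2,
                         tr = 2, duration = 600,
                         bands = canonical_bands("alpha"), seed = 4)
  sim <- simulate_bimodal(cfg)
  lib <- sim$ground_truth$state_library
  loaded <- upper_tri_vec(lib[[1]]) > 0.5 | upper_tri_vec(lib[[2]]) > 0.5
  hp <- hilbert_env_phase(bandpass(sim$fast, cfg$bands[[1]]))
  eeg <- eeg_fc_amp(hp$envelope, tr = 2)
  fmri <- apply_hemodynamic_shift(fmri_edge_series(sim$slow, tr = 2), 6, 2)
  res2 <- edge_temporal_convergence(fmri, eeg, n_perm = 40, seed = 7)
  expect_gt(mean(res2$r[loaded]), mean(res2$r[!loaded]) + 0.05)
})
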