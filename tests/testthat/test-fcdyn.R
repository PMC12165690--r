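make_tone <- function(f, fs = 250, dur = 20, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * cos(2 * pi * f * t)
}

test_that("band-pass filter passes the band center and kills distant tones", {
  fs <- 250
  for (band in canonical_bands(c("delta", "alpha", "gamma"))) {
    fc <- sqrt(band$low * band$high)
    x <- region_signal_set(rbind(make_tone(fc, fs),
                                 make_tone(2 * band$high, fs),
                                 make_tone(band$low / 2, fs)),
                           fs = fs, modality = "fast")
    y <- bandpass(x, band)
    interior <- 1500:3500
    gain_db <- function(row) 20 * log10(max(abs(y$values[row, interior])))
    expect_lt(abs(gain_db(1)), 20 * log10(1.1))  # center within 10 %
    expect_lt(gain_db(2), -40)                   # octave above the high edge
    expect_lt(gain_db(3), -40)                   # octave below the low edge
  }
  x <- region_signal_set(matrix(rnorm(2500), 1), fs = 100, modality = "fast")
  expect_error(bandpass(x, band_spec("gamma", 31, 60)), "Nyquist")
})

test_that("Hilbert transform recovers envelope and phase of known signals", {
  fs <- 250
  tone <- region_signal_set(matrix(make_tone(10, fs, amp = 2.5), 1),
                            fs = fs, modality = "fast",
                            band = band_spec("alpha", 8, 13))
  hp <- hilbert_env_phase(tone)
  interior <- 500:4500
  expect_true(all(hp$envelope$values >= 0))
  expect_equal(mean(hp$envelope$values[1, interior]), 2.5, tolerance = 0.02)

  # unwrapped phase advances at 2*pi*f per second (linear fit oracle)
  tt <- (interior - 1) / fs
  slope <- coef(lm(hp$phase$values[1, interior] ~ tt))[2]
  expect_equal(unname(slope), 2 * pi * 10, tolerance = 0.01)
  expect_true(all(diff(hp$phase$values[1, ]) > -pi))

  # amplitude-modulated tone: envelope recovers the modulator
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  modulator <- 1 + 0.5 * sin(2 * pi * 0.7 * t)
  am <- region_signal_set(matrix(modulator * cos(2 * pi * 10 * t), 1),
                          fs = fs, modality = "fast")
  env <- hilbert_env_phase(am)$envelope$values[1, interior]
  expect_gt(cor(env, modulator[interior]), 0.99)

  zero <- region_signal_set(matrix(0, 1, 100) + 0, fs = fs, modality = "fast")
  zero$values[] <- 0
  expect_error(hilbert_env_phase(zero), "identically zero")
})

test_that("amplitude-coupling frames follow the windowed z-product definition", {
  fs <- 250; tr <- 3
  expect_equal(window_spec(tr, fs, 10 * tr * fs)$n_per_window, 750L)

  # identical envelopes: the self-product averages to ~1 under population
  # z-scoring (windows tile all but the unbalanced boundary samples)
  set.seed(2)
  env_row <- abs(rnorm(20 * tr * fs)) + 0.2
  env <- region_signal_set(rbind(env_row, env_row, abs(rnorm(20 * tr * fs)) + 0.2),
                           fs = fs, modality = "fast")
  amp <- eeg_fc_amp(env, tr = tr)
  self_edge <- amp$frames[, 1] # edge (1,2) between identical channels
  expect_equal(mean(self_edge), 1, tolerance = 0.05)

  # independent white envelopes fluctuate around zero
  expect_lt(abs(mean(amp$frames[, 2])), 0.1)

  # windows that would overrun the recording are dropped
  ws <- window_spec(2, 250, 30 * 500)
  expect_equal(ws$frame_index, 2:30)
  expect_true(all(ws$starts >= 1 & ws$starts + ws$n_per_window - 1 <= 15000))

  env$values[3, ] <- 1
  expect_error(eeg_fc_amp(env, tr = tr), "zero-variance")
})

test_that("windowed frame means match a brute-force loop", {
  fs <- 50; tr <- 2
  set.seed(3)
  env <- region_signal_set(matrix(abs(rnorm(3 * fs * 20)) + 0.1, 3),
                           fs = fs, modality = "fast")
  amp <- eeg_fc_amp(env, tr = tr)
  # brute force: z-score each channel (population), then window means
  z <- t(apply(env$values, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  n <- round(tr * fs)
  k <- 5 # frame index 5, centered at (5-1)*tr
  start <- round((k - 1) * tr * fs - n / 2) + 1
  seg <- z[, start:(start + n - 1)]
  expected <- c(mean(seg[1, ] * seg[2, ]), mean(seg[1, ] * seg[3, ]),
                mean(seg[2, ] * seg[3, ]))
  row <- which(amp$frame_index == k)
  expect_equal(unname(amp$frames[row, ]), expected, tolerance = 1e-12)
})

test_that("phase-locking value obeys its bounds and limiting cases", {
  fs <- 100; tr <- 2
  n <- 20 * fs
  t <- seq_len(n) / fs
  base <- 2 * pi * 10 * t
  # constant offsets (0 and pi/3) lock at exactly 1
  ph <- region_signal_set(rbind(base, base + pi / 3, base), fs = fs,
                          modality = "fast")
  ph$values[3, ] <- cumsum(runif(n, 0, 2 * pi)) # wildly drifting phase
  plv <- eeg_fc_phase(ph, tr = tr)
  expect_equal(plv$frames[, 1], rep(1, nrow(plv$frames)), tolerance = 1e-9)
  expect_true(all(plv$frames >= 0 & plv$frames <= 1))
  # uniformly scattered phase differences decohere towards zero
  expect_lt(max(plv$frames[, 2]), 0.3)
})

test_that("BOLD edge series mean equals the Pearson correlation exactly", {
  set.seed(8)
  bold <- region_signal_set(matrix(rnorm(6 * 40), 6, 40), fs = 0.5,
                            modality = "slow")
  es <- fmri_edge_series(bold, tr = 2)
  ei <- edge_index(6)
  cors <- cor(t(bold$values))
  expect_equal(colMeans(es$frames), cors[cbind(ei$i, ei$j)], tolerance = 1e-12)

  # identical regions: every frame value is z^2 with mean exactly 1
  bold2 <- region_signal_set(rbind(bold$values[1, ], bold$values[1, ],
                                   bold$values[2, ]), fs = 0.5, modality = "slow")
  es2 <- fmri_edge_series(bold2, tr = 2)
  expect_true(all(es2$frames[, 1] >= 0))
  expect_equal(mean(es2$frames[, 1]), 1, tolerance = 1e-12)

  bold$values[2, ] <- 7
  expect_error(fmri_edge_series(bold, tr = 2), "zero-variance")
})

test_that("5-point toy edge series matches hand computation", {
  x <- c(1, 3, 2, 5, 4); y <- c(2, 1, 4, 3, 5)
  pad <- matrix(rnorm(3 * 10), 3, 10)
  set.seed(9)
  vals <- rbind(c(x, rnorm(5)), c(y, rnorm(5)), pad[1, ])
  bold <- region_signal_set(vals, fs = 0.5, modality = "slow")
  es <- fmri_edge_series(bold, tr = 2)
  zx <- (vals[1, ] - mean(vals[1, ])) / sqrt(mean((vals[1, ] - mean(vals[1, ]))^2))
  zy <- (vals[2, ] - mean(vals[2, ])) / sqrt(mean((vals[2, ] - mean(vals[2, ]))^2))
  expect_equal(es$frames[1:5, 1], (zx * zy)[1:5], tolerance = 1e-12)
})

test_that("hemodynamic shift re-indexes by lag/TR frames and composes", {
  e <- 10L
  fr <- matrix(seq_len(20 * e), 20, e)
  s <- edge_frame_series(fr, n_regions = 5, tr = 3)
  sh <- apply_hemodynamic_shift(s, lag = 6, tr = 3)
  expect_equal(nrow(sh$frames), 18)         # 6 s / 3 s = 2 frames
  expect_equal(sh$frames[1, ], fr[3, ])
  expect_true(sh$shifted)

  s2 <- edge_frame_series(fr, n_regions = 5, tr = 2)
  sh2 <- apply_hemodynamic_shift(s2, lag = 6, tr = 2)
  expect_equal(nrow(sh2$frames), 17)        # 6 s / 2 s = 3 frames
  expect_equal(sh2$frames[1, ], fr[4, ])

  expect_identical(apply_hemodynamic_shift(s, 0, 3)$frames, s$frames)
  expect_error(apply_hemodynamic_shift(s, lag = 4, tr = 3), "multiple of TR")

  # shifting back restores the overlapping segment exactly
  back <- apply_hemodynamic_shift(sh, lag = -6, tr = 3)
  common <- intersect(back$frame_index, s$frame_index)
  expect_equal(back$frames, fr[match(common, s$frame_index), ])
})

test_that("canonical HRF kernel and convolution behave as an LTI system", {
  k <- canonical_hrf(dt = 0.1)
  expect_equal(max(k), 1)
  expect_equal((which.max(k) - 1) * 0.1, 6, tolerance = 0.2)
  expect_lt(min(k), 0) # undershoot present
  expect_gt(min(k), -0.5)

  fs <- 10
  imp <- matrix(0, 1, 400); imp[1, 50] <- 1
  sig <- region_signal_set(imp, fs = fs, modality = "fast")
  out <- hrf_convolve(sig)$values[1, ]
  expect_equal(out[50:370], canonical_hrf(1 / fs)[1:321], tolerance = 1e-9)
  expect_equal((which.max(out) - 50) / fs, 6, tolerance = 0.2)

  const <- region_signal_set(matrix(2, 1, 600), fs = fs, modality = "fast")
  outc <- hrf_convolve(const)$values[1, ]
  expect_equal(outc[500], 2 * sum(canonical_hrf(1 / fs)), tolerance = 1e-9)

  # white noise is shaped by the kernel's transfer function (low-pass)
  set.seed(5)
  noise <- matrix(rnorm(4096), 1)
  shaped <- hrf_convolve(region_signal_set(noise, fs = fs, modality = "fast"))
  ratio <- Mod(fft(shaped$values[1, ])) / Mod(fft(noise[1, ]))
  kf <- Mod(fft(c(canonical_hrf(1 / fs), rep(0, 4096 - length(canonical_hrf(1 / fs))))))
  sel <- 10:2000
  expect_gt(cor(ratio[sel], kf[sel]), 0.95)
})

test_that("static FC is the per-edge temporal mean", {
  set.seed(11)
  fr <- matrix(rnorm(15 * 6), 15, 6)
  s <- edge_frame_series(fr, n_regions = 4, tr = 2)
  expect_equal(static_fc(s), colMeans(fr))
  one <- edge_frame_series(fr[1, , drop = FALSE], n_regions = 4, tr = 2)
  expect_equal(static_fc(one), fr[1, ])
})
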