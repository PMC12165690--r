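# Shared small fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small, fast scenario-I recording: 12 regions, 60 frames, two bands
small_cfg <- function(scenario = "I", seed = 11L) {
  scenario_config(scenario = scenario, n_regions = 12L, n_states = 2L,
                  tr = 2, duration = 120, fs_fast = 250,
                  bands = canonical_bands(c("alpha", "beta")), seed = seed)
}

small_sim <- function() cached("small_sim", simulate_bimodal(small_cfg()))

small_fc <- function() cached("small_fc", {
  sim <- small_sim()
  subject_fc(sim$fast, sim$slow, tr = 2, lag = 6,
             bands = small_cfg()$bands)
})

# iid-noise edge series pair (no cross-modal structure), for null calibration
null_series_pair <- function(n_regions = 10L, n_frames = 24L, seed = 5L) {
  set.seed(seed)
  e <- n_regions * (n_regions - 1L) / 2L
  a <- edge_frame_series(matrix(rnorm(n_frames * e), n_frames, e),
                         n_regions = n_regions, tr = 2, coupling = "bold")
  b <- edge_frame_series(matrix(rnorm(n_frames * e), n_frames, e),
                         n_regions = n_regions, tr = 2, coupling = "amp")
  list(a = a, b = b)
}

# structured state-driven frames: template upper triangle + noise, with a
# Markov label sequence; returns per-subject edge series and the labels
structured_frames <- function(n_subjects = 2L, n_frames = 80L, n_regions = 12L,
                              k = 3L, noise_sd = 0.6, seed = 21L) {
  set.seed(seed)
  lib <- make_state_library(n_regions, k)
  tri <- vapply(lib, upper_tri_vec, numeric(n_regions * (n_regions - 1L) / 2L))
  series <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    lab <- rep(seq_len(k), length.out = n_frames)[sample.int(n_frames)]
    frames <- t(tri[, lab]) + matrix(rnorm(n_frames * nrow(tri), sd = noise_sd),
                                     n_frames, nrow(tri))
    series[[s]] <- edge_frame_series(frames, n_regions = n_regions, tr = 2,
                                     coupling = "bold")
    labels[[s]] <- lab
  }
  list(series = series, labels = labels, library = lib)
}
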