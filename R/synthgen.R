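# Synthetic bimodal generator with known cross-timescale convergence
# structure. A shared library of K latent network states (symmetric,
# positive-semidefinite coupling templates) drives both modalities:
#
#   * fast modality: per-band band-limited noise carriers mixed per TR frame
#     through the Cholesky factor of the active state's template
#     (crossfaded over half a TR to avoid discontinuities), summed over
#     bands, plus broadband white noise;
#   * slow modality: state-mixed white latents on a fine grid, convolved
#     with the canonical HRF whose peak latency realizes the hemodynamic
#     lag, sampled at TR, plus white noise.
#
# Three scenarios control the ground-truth convergence: I shares one Markov
# state sequence across all timescales (spatial and temporal convergence),
# II draws an independent sequence per timescale from the shared library
# (spatial convergence only), and III assigns disjoint half-libraries to
# the fast and slow modalities (no convergence).

#' Scenario configuration for the synthetic bimodal generator
#'
#' @param scenario `"I"` (shared state sequence across timescales), `"II"`
#'   (shared repertoire, independent sequences) or `"III"` (disjoint
#'   repertoires).
#' @param n_regions Number of regions R (>= 4).
#' @param n_states Number of latent network states K (>= 2; default 3).
#' @param tr Repetition time of the slow modality in seconds.
#' @param duration Recording length in seconds (>= 20 frames).
#' @param fs_fast Sampling rate of the fast modality in Hz; must exceed
#'   twice the highest band edge.
#' @param bands List of [band_spec()]s (default: the five canonical bands).
#' @param hemo_lag Hemodynamic lag in seconds (default 6), realized through
#'   the canonical HRF peak latency plus an explicit shift for the remainder.
#' @param state_dwell Mean dwell time per state in seconds (default 12).
#' @param snr Ratio of state-driven to noise variance (> 0; default 4).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("II", "I", "III"), n_regions = 30L,
                            n_states = 3L, tr = 2, duration = 400,
                            fs_fast = 250, bands = canonical_bands(),
                            hemo_lag = 6, state_dwell = 12, snr = 4,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_regions >= 4L, n_states >= 2L, tr > 0, duration / tr >= 20,
            state_dwell > 0, hemo_lag >= 0)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  max_edge <- max(vapply(bands, `[[`, numeric(1), "high"))
  if (fs_fast <= 2 * max_edge) {
    stop("fs_fast must exceed twice the highest band edge", call. = FALSE)
  }
  if (abs(hemo_lag / tr - round(hemo_lag / tr)) > 1e-9) {
    stop("hemo_lag must be an integer multiple of tr so the shift can be undone",
         call. = FALSE)
  }
  list(scenario = scenario, n_regions = as.integer(n_regions),
       n_states = as.integer(n_states), tr = tr, duration = duration,
       fs_fast = fs_fast, bands = bands, hemo_lag = hemo_lag,
       state_dwell = state_dwell, snr = snr, seed = as.integer(seed))
}

#' Library of latent network-state coupling templates
#'
#' Draws `n_states` symmetric positive-semidefinite R x R coupling templates
#' with unit diagonal whose upper triangles are pairwise decorrelated
#' (|r| < 0.5), regenerating up to `max_attempts` times. Each template is a
#' modular (community-structured) correlation matrix — elevated coupling
#' within a random partition of regions into modules over a weak non-negative
#' baseline, mimicking intrinsic-connectivity-network states. Couplings are
#' kept non-negative so that amplitude-envelope connectivity (which reflects
#' the magnitude of the underlying coupling) remains monotonically related
#' to the signed coupling seen by the slow modality.
#'
#' @param n_regions Number of regions R (>= 4).
#' @param n_states Number of states K (>= 2).
#' @param seed Optional integer seed.
#' @param max_attempts Bound on regeneration attempts (default 100).
#' @param within,between Within- and between-module coupling (defaults 0.9
#'   and 0.02).
#' @return List of K coupling templates.
#' @export
make_state_library <- function(n_regions, n_states, seed = NULL,
                               max_attempts = 100L, within = 0.9,
                               between = 0.02) {
  stopifnot(n_regions >= 4L, n_states >= 2L, between >= 0, within > between,
            within < 1)
  if (!is.null(seed)) set.seed(seed)
  n_modules <- min(max(2L, round(n_regions / 10)), 4L)
  draw_template <- function() {
    assign <- sample.int(n_modules, n_regions, replace = TRUE)
    same <- outer(assign, assign, `==`)
    c0 <- matrix(between, n_regions, n_regions)
    c0[same] <- within
    diag(c0) <- 1
    # equal-coupling block structure with 0 <= between < within < 1 is PD
    c0
  }
  for (attempt in seq_len(max_attempts)) {
    lib <- replicate(n_states, draw_template(), simplify = FALSE)
    tri <- vapply(lib, upper_tri_vec, numeric(n_regions * (n_regions - 1) / 2))
    sds <- apply(tri, 2, stats::sd)
    if (any(sds == 0)) next  # a degenerate single-module draw
    cc <- stats::cor(tri)
    if (max(abs(cc[upper.tri(cc)])) < 0.5) return(lib)
  }
  stop(sprintf("could not draw %d decorrelated templates for R = %d within %d attempts",
               n_states, n_regions, max_attempts), call. = FALSE)
}

# first-order Markov chain with uniform off-diagonal transition mass and a
# mean dwell time of `dwell` seconds at step `tr`
markov_state_sequence <- function(n_frames, states, tr, dwell) {
  k <- length(states)
  if (k == 1L) return(rep(states, n_frames))
  p_switch <- min(1, tr / dwell)
  pick <- function(v) v[sample.int(length(v), 1L)] # avoid sample()'s scalar rule
  seq_out <- integer(n_frames)
  seq_out[1] <- pick(states)
  for (t in 2:n_frames) {
    if (stats::runif(1) < p_switch) {
      seq_out[t] <- pick(setdiff(states, seq_out[t - 1]))
    } else {
      seq_out[t] <- seq_out[t - 1]
    }
  }
  seq_out
}

# lower Cholesky factors of the state templates (with a small ridge for
# numerical safety)
state_chol <- function(library) {
  lapply(library, function(c0) {
    t(chol(c0 + diag(1e-8, nrow(c0))))
  })
}

# mix region-wise innovations through the per-frame active template with a
# half-TR linear crossfade between consecutive frames' mixing matrices
mix_by_state <- function(innov, state_seq, chols, samples_per_frame) {
  n_frames <- length(state_seq)
  out <- matrix(0, nrow(innov), n_frames * samples_per_frame)
  fade_len <- max(1L, floor(samples_per_frame / 2))
  ramp <- seq(0, 1, length.out = fade_len)
  for (f in seq_len(n_frames)) {
    cols <- ((f - 1L) * samples_per_frame + 1L):(f * samples_per_frame)
    block <- innov[, cols, drop = FALSE]
    cur <- chols[[state_seq[f]]] %*% block
    if (f > 1L && state_seq[f] != state_seq[f - 1L]) {
      prev <- chols[[state_seq[f - 1L]]] %*% block[, seq_len(fade_len), drop = FALSE]
      w <- matrix(ramp, nrow(innov), fade_len, byrow = TRUE)
      cur[, seq_len(fade_len)] <- (1 - w) * prev + w * cur[, seq_len(fade_len)]
    }
    out[, cols] <- cur
  }
  out
}

#' Simulate a bimodal recording with known convergence structure
#'
#' @param config A [scenario_config()].
#' @return List with `fast` and `slow` [region_signal_set()]s and
#'   `ground_truth` (per-timescale state sequences, the state library, and
#'   the lag applied).
#' @export
simulate_bimodal <- function(config) {
  set.seed(config$seed)
  R <- config$n_regions
  K <- config$n_states
  n_frames <- round(config$duration / config$tr)
  band_names <- vapply(config$bands, `[[`, character(1), "name")

  library_all <- make_state_library(R, K)
  if (config$scenario == "III") {
    fast_states <- seq_len(ceiling(K / 2))
    slow_states <- setdiff(seq_len(K), fast_states)
  } else {
    fast_states <- slow_states <- seq_len(K)
  }

  shared_seq <- markov_state_sequence(n_frames, fast_states, config$tr,
                                      config$state_dwell)
  seq_for <- function(states) {
    if (config$scenario == "I") shared_seq
    else markov_state_sequence(n_frames, states, config$tr, config$state_dwell)
  }
  band_seqs <- stats::setNames(lapply(band_names, function(b) seq_for(fast_states)),
                               band_names)
  slow_seq <- if (config$scenario == "I") shared_seq else
    markov_state_sequence(n_frames, slow_states, config$tr, config$state_dwell)

  chols <- state_chol(library_all)
  nyq <- config$fs_fast / 2

  ## fast modality: sum of per-band state-mixed band-limited carriers
  spf <- round(config$tr * config$fs_fast)
  n_samp <- n_frames * spf
  fast <- matrix(0, R, n_samp)
  freq <- (seq_len(n_samp) - 1L) * config$fs_fast / n_samp
  freq <- pmin(freq, config$fs_fast - freq) # fold to [0, Nyquist]
  for (b in seq_along(config$bands)) {
    band <- config$bands[[b]]
    # band-limited noise carriers: white noise spectrally shaped by a
    # cosine-edged band mask (1 Hz roll-off outside the band edges)
    roll <- 1
    mask <- rep(0, n_samp)
    inb <- freq >= band$low & freq <= band$high
    mask[inb] <- 1
    lo_edge <- freq >= band$low - roll & freq < band$low
    mask[lo_edge] <- 0.5 * (1 + cos(pi * (band$low - freq[lo_edge]) / roll))
    hi_edge <- freq > band$high & freq <= band$high + roll
    mask[hi_edge] <- 0.5 * (1 + cos(pi * (freq[hi_edge] - band$high) / roll))
    carrier <- matrix(stats::rnorm(R * n_samp), R, n_samp)
    carrier <- t(apply(carrier, 1L, function(row) {
      y <- Re(stats::fft(stats::fft(row) * mask, inverse = TRUE)) / n_samp
      y / stats::sd(y)
    }))
    fast <- fast + mix_by_state(carrier, band_seqs[[b]], chols, spf)
  }
  noise_sd_fast <- sqrt(length(config$bands) / config$snr)
  fast <- fast + matrix(stats::rnorm(R * n_samp, sd = noise_sd_fast), R, n_samp)

  ## slow modality: state-mixed white latents, HRF-convolved, lag-adjusted,
  ## sampled at TR
  dt <- config$tr / 4
  lat_per_frame <- round(config$tr / dt)
  n_lat <- n_frames * lat_per_frame
  latents <- mix_by_state(matrix(stats::rnorm(R * n_lat), R, n_lat),
                          slow_seq, chols, lat_per_frame)
  kern <- canonical_hrf(dt)
  hrf_peak <- (which.max(kern) - 1L) * dt
  extra_shift <- round((config$hemo_lag - hrf_peak) / dt)
  m <- n_lat + length(kern) - 1L
  kf <- stats::fft(c(kern, rep(0, m - length(kern))))
  bold_fine <- t(apply(latents, 1L, function(row) {
    xf <- stats::fft(c(row, rep(0, m - n_lat)))
    y <- Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n_lat)] / m
    if (extra_shift > 0) c(rep(0, extra_shift), y[seq_len(n_lat - extra_shift)])
    else if (extra_shift < 0) c(y[(-extra_shift + 1):n_lat], rep(0, -extra_shift))
    else y
  }))
  samp_idx <- (seq_len(n_frames) - 1L) * lat_per_frame + 1L
  bold <- bold_fine[, samp_idx, drop = FALSE]
  sig_sd <- stats::sd(as.vector(bold))
  bold <- bold + matrix(stats::rnorm(R * n_frames, sd = sig_sd / sqrt(config$snr)),
                        R, n_frames)

  if (!all(is.finite(fast)) || !all(is.finite(bold))) {
    stop("generated signals are non-finite; check snr and band edges", call. = FALSE)
  }

  labels <- paste0("R", seq_len(R))
  list(
    fast = region_signal_set(fast, fs = config$fs_fast, modality = "fast",
                             region_labels = labels),
    slow = region_signal_set(bold, fs = 1 / config$tr, modality = "slow",
                             region_labels = labels),
    ground_truth = list(
      state_sequence_per_timescale = c(list(slow = slow_seq), band_seqs),
      state_library = library_all,
      lag_applied = config$hemo_lag
    )
  )
}
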