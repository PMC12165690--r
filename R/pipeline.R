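# End-to-end orchestration: simulate (or load) subjects, compute frame-wise
# FC for both modalities, build band-specific and multi-frequency CRPs,
# convergence statistics, state clustering and confound checks, and write a
# tidy results bundle with a JSON manifest. All randomness derives from one
# master seed through fixed per-stage offsets.

stage_seed <- function(master, stage, subject = 0L) {
  offsets <- c(simulate = 11L, crp = 23L, stats = 37L, states = 53L,
               confounds = 71L)
  ((as.integer(master) %% 1000003L) * 97L + offsets[[stage]] +
     1009L * as.integer(subject)) %% 100000007L
}

#' Frame-wise FC for one subject, both modalities, all bands
#'
#' Band-passes the fast signals, extracts Hilbert envelopes (and phases),
#' computes amplitude- (or phase-) coupling edge series per band, the BOLD
#' edge series, applies the hemodynamic shift to the latter, and aligns all
#' series on common TR frames.
#'
#' @param fast Fast-modality [region_signal_set()].
#' @param slow Slow-modality [region_signal_set()] sampled at TR.
#' @param tr Repetition time in seconds.
#' @param lag Hemodynamic lag in seconds (default 6).
#' @param bands List of [band_spec()]s (default canonical five).
#' @param coupling `"amp"` (default) or `"phase"` fast-modality coupling.
#' @return List with `fmri` (shifted edge series) and `eeg_by_band`.
#' @export
subject_fc <- function(fast, slow, tr, lag = 6, bands = canonical_bands(),
                       coupling = c("amp", "phase")) {
  coupling <- match.arg(coupling)
  fmri <- fmri_edge_series(slow, tr = tr)
  fmri <- apply_hemodynamic_shift(fmri, lag = lag, tr = tr)
  eeg_by_band <- lapply(bands, function(band) {
    bp <- bandpass(fast, band)
    hp <- hilbert_env_phase(bp)
    if (coupling == "amp") eeg_fc_amp(hp$envelope, tr = tr)
    else eeg_fc_phase(hp$phase, tr = tr)
  })
  names(eeg_by_band) <- vapply(bands, `[[`, character(1), "name")
  list(fmri = fmri, eeg_by_band = eeg_by_band)
}

#' Run the full analysis on a set of (simulated) subjects
#'
#' Executes simulate -> FC -> CRP -> convergence statistics -> states ->
#' confounds for `n_subjects` independent draws of one scenario, writes tidy
#' CSV outputs plus a JSON manifest to `out_dir`, and returns the results.
#'
#' @param config A [scenario_config()]; its `seed` is the master seed.
#' @param n_subjects Number of simulated subjects (default 3).
#' @param acfg [analysis_config()] settings.
#' @param out_dir Optional output directory; when `NULL` nothing is written.
#' @param run_states Cluster states and compute dissociability (default
#'   TRUE; the costliest stage).
#' @return A `crpdyn_run` list: per-subject results, group tables, manifest.
#' @export
run_full_analysis <- function(config, n_subjects = 3L,
                              acfg = analysis_config(), out_dir = NULL,
                              run_states = TRUE) {
  band_names <- vapply(config$bands, `[[`, character(1), "name")
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg_s <- config
    cfg_s$seed <- stage_seed(config$seed, "simulate", s)
    sim <- simulate_bimodal(cfg_s)
    fc <- subject_fc(sim$fast, sim$slow, tr = config$tr, lag = config$hemo_lag,
                     bands = config$bands)
    stack <- crp_stack(fc$fmri, fc$eeg_by_band, config = acfg,
                       seed = stage_seed(config$seed, "crp", s))
    prof <- diagonal_profile(stack$mfcrp, config = acfg,
                             seed = stage_seed(config$seed, "stats", s))
    jac <- band_jaccard_matrix(stack$mfcrp)

    al0 <- align_frames(fc$fmri, fc$eeg_by_band[[1]])
    r_sync <- stack$bands[[1]]$r
    # square-align the first band's CRP for the similarity timecourse
    sq <- min(dim(r_sync))
    sim_tc <- similarity_timecourse(r_sync[seq_len(sq), seq_len(sq)])
    set.seed(stage_seed(config$seed, "confounds", s))
    conf <- list(
      fc_strength = timecourse_null_correlation(
        sim_tc, fc_strength_timecourse(al0$a)[seq_len(sq)], n_perm = acfg$n_perm),
      static_prominence = timecourse_null_correlation(
        sim_tc, static_prominence_timecourse(al0$a)[seq_len(sq)],
        n_perm = acfg$n_perm)
    )
    subjects[[s]] <- list(
      sim = sim, fc = fc, stack = stack, profile = prof, jaccard = jac,
      confounds = conf,
      union_density = mean(stack$mfcrp$union),
      static_similarity = static_crossmodal_similarity(
        static_fc(fc$fmri), static_fc(fc$eeg_by_band[[1]]))
    )
  }

  shifts <- acfg$shifts
  ratio_tab <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    pr <- subjects[[s]]$profile
    data.frame(subject = s, shift = pr$shift, ratio = pr$ratio,
               null_mean = pr$null_mean, null_sd = pr$null_sd, p = pr$p)
  }))
  bf_tab <- if (n_subjects >= 3L) {
    do.call(rbind, lapply(seq_along(shifts), function(i) {
      obs <- vapply(subjects, function(x) x$profile$ratio[i], numeric(1))
      nm <- vapply(subjects, function(x) x$profile$null_mean[i], numeric(1))
      ok <- is.finite(obs) & is.finite(nm)
      bf <- if (sum(ok) >= 3L && stats::sd(obs[ok] - nm[ok]) > 0) {
        bayes_paired_ttest_bf01(obs[ok], nm[ok], prior_scale = acfg$prior_scale)$bf01
      } else NA_real_
      data.frame(shift = shifts[i], bf01 = bf, n = sum(ok))
    }))
  }

  states_res <- NULL
  if (run_states) {
    fmri_list <- lapply(subjects, function(x) x$fc$fmri)
    states_res <- dissociability_zscore(
      fmri_list, k = 5L, n_surrogates = acfg$n_surrogate_states,
      seed = stage_seed(config$seed, "states"))
  }

  run <- structure(list(
    config = config, acfg = acfg, subjects = subjects,
    ratio_table = ratio_tab, bf_table = bf_tab,
    union_density = vapply(subjects, `[[`, numeric(1), "union_density"),
    states = states_res
  ), class = "crpdyn_run")

  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' @export
print.crpdyn_run <- function(x, ...) {
  cat(sprintf("<crpdyn_run> scenario %s, %d subject(s)\n", x$config$scenario,
              length(x$subjects)))
  cat(sprintf("  union CRP density: %s\n",
              paste(sprintf("%.3f", x$union_density), collapse = " ")))
  i0 <- which(x$ratio_table$shift == 0)
  cat(sprintf("  on-/off-diagonal ratio at shift 0: %s\n",
              paste(sprintf("%.2f", x$ratio_table$ratio[i0]), collapse = " ")))
  if (!is.null(x$states)) cat(sprintf("  state dissociability z: %.1f\n", x$states$z))
  invisible(x)
}

write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$ratio_table, file.path(out_dir, "ratio_profile.csv"),
                   row.names = FALSE)
  if (!is.null(run$bf_table)) {
    utils::write.csv(run$bf_table, file.path(out_dir, "bayes_factors.csv"),
                     row.names = FALSE)
  }
  jac_mean <- Reduce(`+`, lapply(run$subjects, `[[`, "jaccard")) /
    length(run$subjects)
  utils::write.csv(as.data.frame(jac_mean), file.path(out_dir, "band_jaccard.csv"))
  dens <- data.frame(subject = seq_along(run$subjects),
                     union_density = run$union_density,
                     static_similarity = vapply(run$subjects, `[[`, numeric(1),
                                                "static_similarity"))
  utils::write.csv(dens, file.path(out_dir, "density.csv"), row.names = FALSE)
  conf <- do.call(rbind, lapply(seq_along(run$subjects), function(s) {
    cf <- run$subjects[[s]]$confounds
    data.frame(subject = s,
               nuisance = names(cf),
               r = vapply(cf, `[[`, numeric(1), "r"),
               p = vapply(cf, `[[`, numeric(1), "p"))
  }))
  utils::write.csv(conf, file.path(out_dir, "confounds.csv"), row.names = FALSE)
  if (!is.null(run$states)) {
    utils::write.csv(data.frame(z = run$states$z, real = run$states$real),
                     file.path(out_dir, "state_dissociability.csv"),
                     row.names = FALSE)
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("crpdyn")),
    scenario = run$config$scenario,
    master_seed = run$config$seed,
    n_subjects = length(run$subjects),
    settings = run$acfg,
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
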