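---
title: "Cross-modal recurrence analysis of dynamic connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal recurrence analysis of dynamic connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crpdyn)
```

## The question crpdyn addresses

Functional connectivity (FC) between brain regions can be measured at very
different timescales: infraslow BOLD co-fluctuations in fMRI, and amplitude-
or phase-coupling of band-limited electrophysiological signals (delta through
gamma). Whole-brain FC patterns reconfigure over time in both kinds of data.
`crpdyn` implements a frame-wise, cross-modal comparison of these connectome
trajectories that distinguishes three situations:

* **Scenario I — spatially and temporally convergent.** Both timescales
  traverse the same connectome patterns at the same (lag-corrected) times.
* **Scenario II — spatially convergent, temporally divergent.** Both
  timescales visit a shared repertoire of patterns, but asynchronously.
* **Scenario III — spatially and temporally divergent.** The repertoires
  themselves are disjoint.

The central object is the **cross-modal recurrence plot (CRP)**: the matrix
of spatial (edge-wise) Pearson correlations between every fMRI connectome
frame and every band-specific electrophysiological connectome frame. Its
density of significant entries measures spatial convergence; the
concentration of significant entries on the (lag-corrected) diagonal —
the **on-/off-diagonal ratio** — measures temporal convergence.

## Frame-wise connectivity measures

All frame-wise measures use a fixed row-major upper-triangle edge order
(`edge_index()`), serialized with every result.

* **BOLD edge time series** (`fmri_edge_series`): for regions *i*, *j* at
  frame *t*, `fMRI-FC_ij(t) = Z(BOLD_i(t)) * Z(BOLD_j(t))`, where `Z` is the
  z-score over the region's own timepoints. The temporal mean of each edge
  series equals the full-series Pearson correlation — an identity the test
  suite asserts to 1e-12. We use the *population* z-scoring convention
  (divide by T, not T-1) so the identity and the unit self-product mean hold
  exactly; the alternative convention changes nothing else downstream.
* **Amplitude coupling** (`eeg_fc_amp`): band-passed signals are Hilbert
  transformed; envelopes are z-scored over the whole recording, and each
  TR-length window (L = TR, N = round(TR*fs) samples, centered on the TR
  grid) averages the envelope product. Windows that would overrun the
  recording are dropped rather than padded, avoiding envelope edge
  artifacts; the surviving frame indices are carried in the container and
  used to align series.
* **Phase coupling** (`eeg_fc_phase`): the phase-locking value — the modulus
  of the windowed mean unit phasor of the phase difference. The modulus (not
  the real part) is taken, since the complex mean itself is not a bounded
  scalar coupling measure; this is the standard PLV and is 1 exactly when
  the phase difference is constant in the window.
* **Band-pass filtering** (`bandpass`): fourth-order Chebyshev type II
  design with 40 dB stopband attenuation and stopband edges at the band
  limits. The squared magnitude response is applied in the frequency domain,
  which is the zero-phase (forward-backward) application of the filter;
  zero phase matters because phase-locking estimates must not be biased by
  filter delay. The per-band passband/stopband contract (center gain within
  1 dB, at least 40 dB an octave outside the edges) is asserted by tests.
* **Hemodynamic alignment** (`apply_hemodynamic_shift`): the fMRI edge
  series is shifted 6 s backwards in time (2 frames at TR = 3 s, 3 frames at
  TR = 2 s). The lag must be an integer number of frames; overhanging frames
  are dropped, and shifting by the negative lag restores the overlapping
  segment exactly.
* **HRF convolution** (`hrf_convolve`): canonical double-gamma kernel
  (response peak 6 s, undershoot peak 16 s, peak:undershoot 6:1, 32 s
  support, unit peak), used to create hemodynamically smoothed versions of
  band-limited envelopes for the replication analysis at matched temporal
  characteristics.

## CRP statistics

Each band's CRP entry is tested against a **spatial phase-permutation
null**: the frame's symmetric FC matrix is transformed to 2D Fourier space,
its phases are randomized under a conjugate-symmetry constraint (so the
surrogate is real and the amplitude spectrum — hence mean and total variance
— is preserved exactly), re-symmetrized by averaging with its transpose, and
correlated with every electrophysiological frame. The `n_perm = 100` null
CRPs are built once per band; every entry is compared against its own 100
null values with the one-tailed empirical p `(1 + #{null >= obs})/(n_perm+1)`.
Negative observed correlations are excluded (p = 1): spatial
anti-correlation of whole-connectome patterns is not interpreted.
Benjamini–Hochberg FDR (q = 0.05) is applied jointly over all S x S epochs
of one band's CRP; the per-band binary layers are OR-ed into the
multi-frequency CRP.

A consequence worth knowing: with empirical p-values floored at
1/(n_perm+1) = 1/101, BH over S^2 epochs can only pass entries sitting at
the floor, and only when the floored fraction exceeds roughly
1/(101 q) ≈ 20%. The binarization therefore behaves almost discretely at
the per-band level — which matches the reported behavior of this design in
real recordings, and which the synthetic generator's operating point is
chosen to clear (below).

Temporal convergence is quantified by `on_off_ratio` (single shifted
diagonal, no guard band; entries cut off by the shift contribute to
neither count) over shifts of -5..+5 TR, against ratios of 100
**density-matched CRP surrogates**: each binary layer is phase-randomized as
a real 2D field and re-binarized at the count-preserving quantile, because
the ratio statistic conditions on density. Subject-level significance uses
the same one-tailed empirical p; group-level evidence *for* temporal
divergence uses a one-tailed JZS Bayes factor (`bayes_paired_ttest_bf01`,
Cauchy prior scale 0.707, H1: ratio > null), computed by numerical
integration of the non-central-t likelihood over the truncated prior and
cross-checked in tests against a Monte-Carlo integration oracle.
Inter-band overlap uses the Jaccard index of binary layers.

## Recurrent states and their dissociability

Frames are pooled across subjects per timescale and clustered with
Euclidean K-means (20 restarts; K = 5 with K = 7 for replication is the
convention for real data; the synthetic tests use the generator's true K).
The frame proximity matrix (pairwise Pearson similarity, sorted by label)
is compared with the ideal binary within-cluster indicator; the Pearson
correlation of the off-diagonal entries is the **dissociability**. Its
z-score against 50 surrogate data sets — per-subject temporal phase
permutation of every edge timecourse (which preserves each edge's mean,
i.e. the static connectome, exactly, while destroying frame patterns),
re-pooled and re-clustered with fresh restarts — tests whether discrete
recurrent states exist beyond static structure. We use similarity rather
than distance for the proximity matrix (sign conventions documented in the
function help) and exclude the diagonal from the correlation.

## Confound checks

The synchronous similarity timecourse (the CRP diagonal) is correlated with
per-frame FC strength (root-sum-square over edges), framewise displacement
(FD = sum of absolute translation differences + 50 mm x sum of absolute
rotation differences — the standard radius, which the source formulation
leaves implicit), and static-connectome prominence (per-frame correlation
with the static FC vector). Significance uses two-sided empirical p against
100 Fourier phase-randomizations of the similarity timecourse. Artifact
epochs are compared with the binarized similarity timecourse (union-layer
significance of the diagonal entry) via Jaccard against a circular-shift
null (shift 0 excluded; shifts drawn without replacement when possible).
The within-network (ICN) strength illustration averages within-network
edges per frame, z-scores over frames, and marks emergence at z > 2.

## The synthetic generator

No generative model is prescribed for the three scenarios — they are
conceptual — so the generator is an explicit design of this package, built
to make ground truth unambiguous rather than biophysically detailed:

* **State library** (`make_state_library`): K symmetric positive-definite
  coupling templates with unit diagonal, each a modular (community / ICN-
  like) correlation matrix — a random partition of the R regions into
  roughly R/10 modules with within-module coupling 0.9 over a 0.02
  baseline — regenerated until all pairwise upper-triangle correlations are
  below 0.5. Couplings are non-negative by design: amplitude-envelope FC of
  linearly mixed carriers reflects the squared mixing correlation, so with
  signed zero-mean templates the envelope pattern would be *uncorrelated*
  with the BOLD pattern and no scenario could produce cross-modal
  convergence; non-negative modular templates keep the two modalities'
  patterns monotonically related, as in real cortical FC, and the high
  within-module contrast puts ground-truth convergence safely above the
  FDR granularity discussed earlier.
* **State dynamics**: a first-order Markov chain with uniform off-diagonal
  transition mass and mean dwell 12 s — slow, recurring states of the kind
  sliding-window studies report.
* **Fast modality**: per band, independent unit-variance band-limited noise
  carriers (white noise spectrally shaped by a cosine-edged band mask) are
  mixed per frame through the Cholesky factor of the active template,
  crossfaded over half a TR at state switches to avoid discontinuities,
  summed over bands, plus broadband white noise at the configured
  signal-to-noise ratio (default 4, i.e. state-driven variance four times
  the noise variance).
* **Slow modality**: white latents on a TR/4 grid mixed the same way,
  convolved with the canonical HRF. The hemodynamic lag (default 6 s) is
  realized by the HRF's own peak latency plus an explicit shift for any
  remainder, so the analysis-side 6 s back-shift compensates it exactly;
  a naive "HRF plus separate 6 s delay" would double-lag the data.
* **Scenarios**: I shares one state sequence across all timescales; II
  draws an independent sequence per timescale (one per band plus one for
  BOLD) from the shared library; III assigns disjoint half-libraries to the
  fast and slow modalities.

What the generator does *not* emulate: 1/f background spectra, volume
conduction / source leakage, non-Gaussian bursts, epileptiform events,
physiological noise, or a biophysical BOLD model. Passing tests on this
generator therefore demonstrate that the statistical machinery recovers
known convergence structure under idealized noise — not that any particular
real dataset follows one scenario.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at R = 30 regions, S = 200
frames (TR 2 s, 250 Hz fast modality, five canonical bands), with 20
scenario-I replicates, 10 scenario-II replicates and 5 scenario-III
replicates at vanishing snr; unit tests use smaller configurations (R = 10
to 12, S = 60). Empirical p-values always use the +1/(n+1) correction; all
surrogate constructions draw conjugate-symmetric phases so spectra are
preserved to machine precision; K-means surrogate clustering re-runs with
fresh restarts so clustering variability enters the null; undefined
on-/off-diagonal ratios (empty off-diagonal) propagate as NA and are
excluded from group summaries with a warning. All randomness flows from a
single master seed via fixed per-stage offsets (`run_full_analysis`), and
every stage is bitwise reproducible given its seed.

This package is an R analysis library in the Bioconductor mold: the
exported functions, `run_full_analysis`, and this vignette are the
interface; the only shell entry point is `scripts/acceptance.R`, which
regenerates the headline calibration quantity from scratch.

## Known limitations

* The FDR binarization inherits the granularity of 100-permutation
  empirical p-values: weak but genuine convergence below the ~20% floored
  fraction yields an empty CRP layer rather than a sparse one.
* Envelope coupling of the generator maps template coupling through an
  approximately quadratic transform; only the monotone relation, not the
  exact value, is matched across modalities.
* `eeg_fc_phase` is computed and tested, but the generator's ground truth
  is designed around amplitude coupling; phase-coupling recovery is weaker.
* The generator's state signal lives in fast, instantaneous envelope
  co-fluctuations. HRF-convolving each region's envelope (the
  `hrf_convolve` replication route) smooths the regions independently and
  removes most of that shared fast component, so connection-level
  convergence is validated with the lag-shifted raw-envelope route and
  constructed fixtures; real recordings, whose envelopes carry genuine
  infraslow co-fluctuations, are not limited this way.
* Negative cross-modal correlations are excluded by design, following the
  analysis convention.
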