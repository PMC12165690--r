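Package: crpdyn
Title: Cross-Modal Recurrence Plot Analysis of Dynamic Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise functional connectivity at hemodynamic (BOLD-like) and
    electrophysiological timescales, cross-modal recurrence plots (CRPs) with
    permutation-based significance and false-discovery-rate binarization,
    on-/off-diagonal convergence statistics with surrogate nulls and one-tailed
    JZS Bayes factors, inter-band overlap (Jaccard), recurrent connectome-state
    clustering with phase-permutation dissociability tests, and nuisance
    (motion, FC-strength, static-prominence, artifact-epoch) checks. Includes a
    synthetic bimodal signal generator with known ground-truth convergence
    scenarios for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
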