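Package: eegpli
Title: Surrogate-Corrected Phase-Lag Connectivity and Lempel-Ziv
    Complexity for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of weighted and directed phase lag indices (wPLI,
    dPLI) in the alpha band from multichannel EEG, with surrogate-data
    significance correction, node-degree hub topography, frontoparietal
    feedback-dominance summaries, and three Lempel-Ziv complexity
    estimators (median univariate, concatenated, joint) normalized by
    phase-randomized surrogates.  Includes a synthetic-EEG generator with
    known directed phase-lag structure, volume-conduction contamination
    and controllable signal compressibility, plus paired
    baseline/anesthesia scenarios with ground-truth expected directions
    of change, and a case pipeline that classifies canonical versus
    paradoxical anesthetic responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
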