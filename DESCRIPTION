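Package: eegfuse
Title: Fused Functional and Effective EEG Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discriminates two subject groups from multi-trial epoched EEG by
    fusing phase lag index (PLI) functional connectivity with partial directed
    coherence (PDC) effective connectivity. Provides Morlet wavelet
    time-frequency decomposition with baseline normalization and a
    cluster-based permutation comparison of group power maps; trial-ensemble
    multivariate autoregressive (MVAR) estimation via the multivariate
    Yule-Walker equations with BIC order selection; PDC spectra with
    phase-randomized surrogate significance thresholds; Fisher-score feature
    selection over single-estimator and combined strategies; leave-one-out
    cross-validated linear support vector machine classification with a
    modified permutation significance test; and a seeded synthetic two-group
    study generator with known directed and phase-coupling ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    pROC,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
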