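Package: eegentropy
Title: Entropy-Based Classification and Monitoring of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for entropy-based analysis of multichannel resting-state
    EEG, built around a Parkinson's disease versus control classification
    workflow. Provides a seeded two-class EEG cohort simulator with
    controllable band-power and irregularity profiles, Butterworth band-pass
    preprocessing with amplitude-threshold artifact rejection and
    segmentation, db4 discrete-wavelet subband signal reconstruction, seven
    entropy estimators (singular-value decomposition, permutation, sample,
    cosine-similarity, fuzzy, phase, and attention entropy), per-segment
    feature assembly over channel-by-subband grids, a two-stage repeated
    stratified K-fold support-vector classification protocol, greedy forward
    feature selection, and entropy-trajectory monitoring utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    digest,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
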