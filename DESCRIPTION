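Package: rsnica
Title: ICA-Based Repeated-Measures Analysis of Resting-State Network Amplitude
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for repeated-measures resting-state fMRI
    studies analysed with per-scan spatial independent component analysis:
    temporal high-pass filtering and RETROICOR-style nuisance regression,
    per-scan PCA-reduced spatial ICA with z-scored component maps,
    hierarchical clustering of components into group resting-state network
    templates from baseline scans only, goodness-of-fit best-component
    selection, a combined within-subject contrast with Monte-Carlo
    cluster-extent correction, regional-score extraction, and
    behaviour/ANCOVA coupling. Ships a synthetic-study generator that
    plants known regional amplitude enhancements and suppressions so every
    stage of the pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
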