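Package: whalenet
Title: Whale-Optimization-Tuned Convolutional Ensembles for Multi-Class
    Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hyperparameter optimization of convolutional image classifiers
    with the Whale Optimization Algorithm (WOA), and combination of the tuned
    classifiers by a soft-voting ensemble.  Provides the normalized-cube
    hyperparameter codec, the WOA optimizer with encircling, spiral and
    exploration updates, a compact CNN training engine (a from-scratch
    lightweight vision model and frozen-backbone transfer heads), partial-
    training validation-loss fitness, patient-level stratified splitting with
    balance-targeted augmentation, a seeded synthetic three-class MRI-like
    cohort generator, per-class one-vs-rest evaluation metrics with macro
    aggregation and Wald confidence intervals, and a staged, resumable
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
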