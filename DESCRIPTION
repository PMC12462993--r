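Package: graspflow
Title: Tactile Information Flow Between Sensory and Motor Cortex During Grasping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for directed tactile information transfer
    between primary somatosensory (S1) and primary motor (M1) cortex during
    grasping. Provides sliding-window two-way ANOVA effect decomposition of
    spike-train tuning to texture and load, population decoding with
    unit-dropping curves, non-parametric conditional Granger causality from
    multitaper spectra via Wilson spectral factorization with spike-jitter
    significance testing, pulse-triggered characterization of M1 responses to
    intracortical microstimulation (ICMS) in S1, principled selection of
    distinguishable/confusable/weak stimulation-site pairs, and normalized
    indices of ICMS effects on neural representation, force decoding and
    actual grip force. A synthetic-session generator with a ground-truth
    registry emulates the study design so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
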