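Package: xmodal
Title: Rule-Dependent Neural Population States in a Cross-Modal Sensory
    Selection Task
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of rule-dependent neural population
    activity in a cross-modal (tactile/visual) sensory selection task.
    Provides a Poisson task-and-spiking generator with block-alternating
    rules and a behavioral agent; trial-outcome scoring, detection
    sensitivity and rule-transition parsing; spike binning, smoothing and
    soft normalization; single-unit ideal-observer (ROC/AUC)
    discriminability with bootstrap and Bonferroni rules; cross-validated
    population decoding (LDA, linear SVM, bagged trees) with shuffle
    controls and transition-state classification; population geometry
    (trajectory distances, subspace overlap via variance alignment,
    stimulus and choice coding dimensions); and hierarchical-bootstrap and
    permutation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
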