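Package: mepmuscle
Title: Muscle Classification of Intraoperative Motor-Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, preselection, representation, classification and
    explanation of intraoperative motor-evoked potentials (MEPs). Generates
    synthetic bicentric MEP cohorts with muscle-specific onset latencies and
    main frequencies, applies rule-based MEP preselection, derives filtered
    time-series, engineered-feature and Mexican-hat wavelet scalogram
    representations, trains random-forest and compact convolutional network
    classifiers with patient-stratified splits and class weighting, and
    explains the fitted models with impurity importances, exact tree Shapley
    attributions and gradient class-activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    signal,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
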