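Package: prfbio
Title: Probabilistic Random Forests for Bioactivity Data with
    Experimental Label Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains probabilistic random forest classifiers on bioactivity
    data in which the activity label of each compound is a probability
    rather than a binary call. Potency measurements (pActivity, the
    negative log10 molar IC50/EC50/Ki/Kd) are converted into soft class
    labels through the cumulative normal distribution centred on an
    activity threshold with a standard deviation reflecting experimental
    error. The forest propagates these label probabilities through a
    probability-weighted Gini impurity during tree construction and
    through probability-mass propagation at prediction time, degenerating
    exactly to a classical random forest when labels are binary. Includes
    a replicate-variability audit for activity tables, benchmarking
    statistics (error margins and relative scores against ideal
    probability labels over train/test noise grids), a synthetic
    bioactivity-data generator with sphere-exclusion putative inactives,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
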