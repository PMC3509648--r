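Package: qsrr
Title: Quantitative Structure-Retention Relationship Modelling for Phenolic Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating quantitative
    structure-retention relationship (QSRR) models of reversed-phase
    liquid chromatographic retention times, centred on naturally
    occurring phenolic compounds. Computes the molecular descriptor
    families that drive phenolic retention (Narumi harmonic index,
    distance-magnitude information content, mean carbon-scaled
    polarizability, Geary autocorrelations, centre-of-property
    displacement, 3D-MoRSE signals), pretreats descriptor matrices,
    performs unsupervised forward selection and stepwise multiple
    linear regression, trains small feed-forward neural network
    ensembles with early stopping, and validates models by
    leave-one-out cross-validation, external prediction (PRESS and
    Q-squared) and y-scrambling. Ships a curated 39-compound phenolic
    retention dataset and a synthetic-data generator so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineR
Suggests:
    ChemmineOB,
    igraph,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
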