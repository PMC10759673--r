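Package: thalscreen
Title: Evaluation and Ranking of Red-Cell Indices for Beta-Thalassemia
    Trait Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating discriminant red-cell index formulae used
    to screen for the beta-thalassemia carrier state on complete blood
    count (hemogram) data. Provides a declarative registry of 42 published
    discriminant indices with their cut-offs, confusion-matrix based
    performance measures (sensitivity, specificity, Youden index, AUC,
    accuracy, predictive values, false omission rate), Shannon-entropy
    criterion weighting, and three multi-criteria decision-making ranking
    methods (TOPSIS, COPRAS, SECA) for choosing among indices. Includes a
    two-step mass-screening rule combining a mean corpuscular volume gate
    with the SCS_BTT composite score, false-negative range profiling, and
    a seeded synthetic hemogram cohort generator for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
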