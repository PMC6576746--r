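Package: winoccf
Title: Weighted Imputed Neighborhood-Regularized One-Class Collaborative
    Filtering for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale prediction of drug off-targets from positive-only
    chemical-protein association data. Standardizes heterogeneous bioactivity
    records (IC50, Ki, pKi, percent inhibition) into a sparse one-class
    interaction matrix, augments its unobserved entries with putative
    interactions from binding-site-similarity and docking screens, and
    factorizes the result under a weighted, graph-Laplacian-regularized
    nonnegative low-rank model. Includes dose-response curve fitting (Hill
    binding model and four-parameter sigmoid; Kd, EC50, IC50, GI50, activity
    area), kinome-panel evaluation utilities, drug-sensitivity differential
    expression statistics with gene-set over-representation analysis, and
    seeded synthetic-data generators for all input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    minpack.lm,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
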