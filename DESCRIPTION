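Package: omicage
Title: Multi-Compartment Omic Aging Clocks and Aging Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to build and interrogate chronological-age predictors
    ("aging clocks") from proteomic and metabolomic abundance matrices
    measured across physiological compartments (plasma, urine, skeletal
    muscle).  Implements below-LOD and assay-level quality control,
    covariate-adjusted per-feature age association with
    Benjamini-Hochberg correction, repeated cross-validated elastic-net
    age predictors with permutation-based model- and feature-level
    empirical significance, residual-based aging scores with
    acceleration flagging, compartment composite scores, a Spearman
    screen of scores against clinical covariates, and leave-one-out
    validation of fixed signatures.  A synthetic multi-block cohort
    generator with known ground truth (a latent biological-age deviation
    shared across compartments) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
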