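Package: fpbench
Title: Benchmarking Molecular Fingerprints for Drug Combination Response
    Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative evaluation of rule-based and data-driven molecular
    fingerprints. Generates folded circular (Morgan) and path-based
    topological fingerprints through OpenBabel, trains a graph autoencoder
    with a singular-value fingerprint construction and a SMILES variational
    autoencoder at desk scale, quantifies fingerprint-matrix similarity with
    linear-kernel HSIC and centered kernel alignment (CKA), benchmarks
    fingerprints in drug-combination sensitivity and synergy regression with
    Fisher-z and bootstrap confidence intervals, and scores class-based
    clustering with one-versus-all linear discriminant projections evaluated
    by Silhouette and the variance ratio criterion. Ships a synthetic-data
    module that emulates combination screens with a planted, tunable
    structure-to-response signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    MASS,
    mixOmics,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
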