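Package: mdlatent
Title: miRNA-Disease Association Prediction from Latent and Similarity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a sparse
    binary association matrix. Disease semantic similarity is computed from a
    disease-ontology directed acyclic graph by a decaying ancestor-contribution
    recursion, miRNA functional similarity by best-match averaging over
    associated disease sets, and low-dimensional latent features of miRNAs and
    diseases are learned from the rows and columns of the association matrix
    with a stacked autoencoder carrying a contractive (Jacobian-norm) penalty.
    Per-pair feature vectors fuse latent codes with similarity profiles and are
    classified with gradient boosting; baseline classifiers, five-fold
    cross-validation with leakage control, ablation modes, per-disease
    candidate ranking, and a synthetic-data generator with planted block
    structure are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    e1071,
    optparse,
    pROC,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
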