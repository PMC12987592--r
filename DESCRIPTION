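Package: circDrugGSL
Title: circRNA-Drug Sensitivity Association Prediction via Collaborative
    Feature Learning and Graph Structure Learning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts associations between circular RNA (circRNA) expression
    and drug sensitivity from a sparse binary association matrix, circRNA
    host-gene sequences and drug molecular fingerprints. Six similarity
    kernels (Levenshtein sequence similarity, Tanimoto fingerprint
    similarity, entropy-profile similarity and Gaussian interaction profile
    kernels for both entity types) feed per-source graph-convolutional
    autoencoders coupled by shared must-link constraints; a
    full-graph-parameterised structure learner with dual-view augmentation
    and confidence-gated pseudo-labelling refines the bipartite topology; a
    graph-convolutional prediction head scores every circRNA-drug pair.
    Includes k-fold cross-validation with leakage-guarded kernel
    recomputation, standard link-prediction metrics, and a synthetic-data
    generator with planted low-rank cluster structure for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
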