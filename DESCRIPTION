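Package: ginplans
Title: Graph-Embedding Fingerprints and Partially-Labeled Noisy-Student
    Training for QSAR Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for semi-supervised quantitative structure-activity
    relationship (QSAR) modeling from SMILES. Provides extended-connectivity
    fingerprints (ECFP) and featurized molecular graphs; a Graph Isomorphism
    Network (GIN) pretrained by self-supervised ECFP reconstruction whose
    pooled hidden state yields a continuous 300-dimension fingerprint (GINFP);
    a combination-class label algebra for multi-target binary activity panels
    with partial-label candidate enumeration and completion; mixup
    augmentation; and a partially-labeled noisy-student (PLANS) self-training
    loop with staged multilayer perceptron students, pseudo-label class
    balancing and imbalance-aware evaluation metrics. A synthetic-molecule
    generator with planted substructure-based activity labels makes the whole
    pipeline testable without external assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
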