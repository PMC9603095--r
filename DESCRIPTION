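Package: rlpcascade
Title: Three-Stage Classification of Plant Receptor-Like Proteins with
    Conjugate Bayesian Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences as receptor-like proteins (RLPs)
    through a topology-gated, three-stage cascade: RLP versus non-RLP,
    RLP versus receptor-like kinase (RLK), and RLP subfamily assignment.
    Member classifiers trained on six residue-frequency encodings (amino
    acid, dipeptide and tripeptide composition, side-chain property
    groups, each whole-sequence and split N/C-terminal) are combined by
    conjugate Bayesian inference: Beta-Binomial posteriors over binary
    ensemble votes and a Dirichlet-Multinomial posterior over subfamily
    votes. Includes SMOTE class balancing, stratified cross-validation
    with a full confusion-matrix metric suite, a CD-HIT-style redundancy
    filter, hydropathy-based signal-peptide and transmembrane heuristics
    with pluggable external annotations, and a synthetic corpus generator
    so the whole cascade can be trained and benchmarked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
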