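Package: pugrank
Title: Phenotype-Related Gene Prioritization by Positive-Unlabeled Learning on Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes genes related to a phenotype observed after a gene
    knock-out. Reliable positive genes are selected with strict differential
    expression cutoffs and random-walk-with-restart network propagation;
    false negatives among the unlabeled genes are then rescued by
    positive-unlabeled learning on the gene interaction network, alternating
    loopy belief propagation on a pairwise Markov network with a graph
    attention classifier and class-prior re-estimation. Cross-validated
    rankings are combined by weighted distance-based rank aggregation
    (with Borda and median-rank alternatives) and scored with partial AUC.
    Includes a synthetic benchmark generator with a planted phenotype module
    and matching wild-type/knock-out expression so the whole pipeline can be
    exercised offline, plus RWR and DIAMOnD baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
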