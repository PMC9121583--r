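Package: TopoCurate
Title: Topology-Guided Curation of Gene Expression Cohorts and Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Persistent-homology-guided curation of gene expression matrices.
    Builds Vietoris-Rips filtrations on cohort or gene point clouds, computes
    Z/2 persistence pairings with explicit creator and destroyer simplices,
    extracts representative 1-cycles (shortest cycle at birth) and minimal
    persistent 2-cycles (minimum cut on the dual flow network of a
    pseudo-manifold), selects topologically relevant cohorts through dominant
    cycles and topologically relevant genes through an exact minimum set-cover
    statistic over functional annotations, and quantifies the effect of both
    curations with repeated cross-validated classifiers and a small
    one-dimensional convolutional network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    rpart,
    e1071,
    optparse,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
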