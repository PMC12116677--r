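Package: coresel
Title: Coreset Selection from Image Embeddings by K-Means Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects a small, maximally representative subset (a coreset) of an
    unlabeled image collection for manual annotation by clustering precomputed
    image embeddings with K-means and sampling from the clusters. Ships the
    selection strategies (number of clusters equal to the coreset size, to the
    class count, or to twice the class count, plus a random baseline), the
    per-cluster allocation rule, subset-size arithmetic, cluster-validity
    indices (Davies-Bouldin, silhouette), macro-averaged F1, a class-coverage
    analysis, a repeated-split benchmark against random reduction, and a
    synthetic-embedding generator emulating strongly imbalanced multi-class
    pools, so the whole pipeline is testable without image downloads. A
    command-line entry point exposes every stage with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
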