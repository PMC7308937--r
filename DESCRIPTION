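Package: clustergrow
Title: Iterative Cluster-Based Annotation of Image Feature Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for annotating large collections of objects
    (for example plankton images) from their deep feature vectors. Dense
    regions of the feature space are extracted as cluster seeds by
    hierarchical density-based clustering with a shrinking minimum cluster
    size, validated by an annotator, and grown outward by a paged
    galloping-plus-binary-search protocol around each seed centroid.
    Validated clusters are arranged by average-linkage (UPGMA) clustering of
    their centroids into a hierarchy that supports merge, move and name
    edits and flattens to an object-level labeling. Includes a simulated
    annotator backed by a ground-truth label table, a long-tailed
    Gaussian-mixture benchmark generator, and evaluation tools (macro
    precision, relative overlap, label correspondence, throughput and
    class-recovery reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ape,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
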