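Package: xsconcord
Title: Cross-Species Transcriptional Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcriptional signatures of a disorder
    across species and exposure stages. Implements empirical-Bayes moderated
    differential expression with threshold classification, signed stratified
    rank-rank hypergeometric overlap (RRHO) between two ranked signatures,
    weighted co-expression module detection (soft-thresholded adjacency,
    topological overlap, tree cut), module differential connectivity with a
    two-scheme permutation null, Fisher's-exact module/DE enrichment and
    over-representation analysis against GMT gene-set collections, mutual-
    information hub networks pruned by the data-processing inequality, and
    AUCell-style module scoring of cell profiles. A synthetic-data generator
    plants known differential-expression, cross-cohort concordance, module,
    and connectivity-change structure so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
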