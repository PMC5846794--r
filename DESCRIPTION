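Package: serosig
Title: Rank-Based Serum Proteomic Signatures and Network Analysis for
    Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein biomarker panels from case/control serum
    proteomic abundance matrices using per-subject rank signatures compared
    with a weighted enrichment-score distance, group-average classification
    under stratified cross-validation, label-permutation significance testing,
    and a genetic optimizer that returns a short (parsimonious) and a long
    (pathway-oriented) panel. A network layer extracts transcription-factor
    rooted sub-networks that preferentially route through differentially
    abundant proteins, performs pathway over-representation and tissue
    specificity analysis, and tests seed-gene to pathway proximity against an
    empirical null of random network genes. Includes generators for synthetic
    cohorts, interaction networks, gene-set collections, and tissue expression
    tables with recorded ground truth, so the whole pipeline is testable
    without access to proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
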