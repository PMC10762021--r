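Package: cnvformer
Title: Transformer-Based Per-Exon Copy Number Variant Calling from Exome Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls germline and somatic copy number variants (deletions and
    duplications) at single-exon resolution from whole-exome sequencing read
    depth. A transformer encoder with chromosome-specific classification
    tokens and absolute-coordinate sinusoidal positional encoding classifies
    each capture target as deletion, duplication or no-call from its
    standardized per-base depth signal; exons without depth are resolved by a
    3-nearest-neighbour majority vote and consecutive same-call exons are
    merged into segments. Includes Adam/cosine-annealing training and
    fine-tuning for regime transfer, a macro-averaged exon-level benchmarking
    suite, gradient-weighted attention relevance maps for call
    interpretation, and a negative-binomial exome depth simulator so the full
    pipeline is trainable and testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
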