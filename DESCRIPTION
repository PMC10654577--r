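Package: clonospace
Title: Spatial T Cell Receptor Repertoires from Long-Read Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs T cell receptor (TCR) repertoires from
    nanopore-like long reads captured on barcoded spatial transcriptomics
    arrays and analyses their spatial organisation.  Provides
    adapter-anchored demultiplexing with directional UMI deduplication,
    read reorientation and splitting, lightweight V-J-C annotation with
    CDR3 extraction, partitioned consensus error correction, Levenshtein
    clonotype clustering with per-cell UMI normalisation, Delaunay
    neighbourhood statistics (clonality index, spot-wise CDR3 diversity,
    expansion/diversity spot classification), cell-type-specific
    expression enhancement, clone-by-state matrices, composite
    cytotoxic/exhausted spot scoring, and Kullback-Leibler receptor-ligand
    co-localisation ranking.  A seeded synthetic-data generator emulates
    hexagonal spot lattices, planted clones with locally expanded or
    dispersed spatial patterns, and a configurable
    substitution/insertion/deletion error channel, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
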