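Package: vdjmap
Title: Immune Repertoire Analysis: V(D)J Assignment, Clonotyping, Somatic
    Hypermutation and D50 Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An amplicon-based immune repertoire (AIRR-seq) analysis pipeline
    for mouse immunoglobulin heavy chain (IgH) and T-cell receptor beta (TRB)
    sequencing libraries. Paired-end reads are demultiplexed by 5' constant
    region barcodes, quality-trimmed with a two-base sliding window, merged by
    exact-overlap alignment, and collapsed to unique transcripts. Unique
    sequences are assigned germline V, D, J and C segments by affine-gap
    Smith-Waterman alignment; CDR3 boundaries are migrated from germline
    anchors onto reads, clonotypes aggregated, somatic hypermutation counted
    over the CDR2-to-CDR3 window under a copy-number filter, isotype
    composition and D50 clonal diversity computed, and clonal structure
    rendered as nested V / V-J / V-J-CDR3 tree-maps in SVG. A ground-truthed
    repertoire and read simulator is included so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
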