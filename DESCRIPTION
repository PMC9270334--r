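Package: scpcor
Title: Joint Single-Cell Chromatin Occupancy and RNA Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and joint analysis of scPCOR-seq data, an assay that
    profiles chromatin occupancy (ChIC-style histone-mark or transcription
    factor cleavage fragments) and RNA from the same single cell.  The
    package demultiplexes the dual-modality read structure (inline cell
    barcode, read2 linker, RNA primer motifs, 6-nt UMI), deduplicates
    alignments into per-cell UMI-by-gene and fragment-by-peak count
    matrices, computes per-cell quality metrics and two-species (barnyard)
    collision rates, applies the feature and cell inclusion rules,
    normalizes and reduces each modality, and jointly clusters cells with a
    multiplex-modularity Louvain algorithm on z-scored cell-cell
    correlation networks.  A synthetic-read simulator with complete truth
    tables makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    uwot,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
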