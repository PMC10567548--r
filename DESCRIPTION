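Package: spatialcite
Title: Demultiplexing and Quantification for Spatial CITE-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for processing paired-end sequencing reads from
    spatially barcoded co-assays of proteins (antibody-derived tags, ADTs) and
    transcripts. Reads carry a two-level deterministic spatial barcode (row
    barcode A, column barcode B) identifying a 25-micron tissue pixel.  The
    package parses the barcode read, error-corrects barcodes against
    whitelists, assigns payloads to antibodies or genes, collapses unique
    molecular identifiers (UMIs), and emits sparse spatial count matrices per
    modality, together with per-pixel quality metrics, centred log-ratio (CLR)
    normalization for protein counts, log-normalization for RNA, gene
    signature scoring, and pseudo-bulk aggregation.  A synthetic-data
    generator produces FASTQ libraries from a ground-truth tissue model so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
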