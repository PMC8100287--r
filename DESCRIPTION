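Package: promarch
Title: Promoter Chromatin Architecture from Differential MNase-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of promoter chromatin architecture from paired-end
    MNase-seq fragment data captured around transcription start sites.
    Builds TSS-anchored nucleosome occupancy and differential MNase
    sensitivity (log2 light/heavy) matrices, classifies promoters by
    k-means clustering with dependent sorting and cross-condition
    transition tables, calls subnucleosomal-fragment enrichment peaks
    with a local-lambda Poisson model, scans peak summits against a
    position-weight-matrix motif library, and estimates WW-dinucleotide
    rotational-phasing periodicity from nucleosome-core fragments. A
    synthetic-data generator with full ground truth (promoter classes,
    nucleosome stability, TF footprints, planted sequence periodicity,
    expression) makes every stage testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
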