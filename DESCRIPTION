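Package: idxcov
Title: Whole-Genome Coverage Estimation and Cohort QC from Alignment Indexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates relative whole-genome sequencing depth in 16384-bp
    tiles directly from the byte layout of BAM (.bai) and CRAM (.crai)
    alignment indexes, without decoding a single alignment record.  The
    per-tile compressed byte counts recorded between consecutive linear-index
    offsets act as a proxy for read depth; after median scaling they support
    cohort-level quality control: sex-chromosome copy-number estimation and
    sex inference, detection of aberrant coverage profiles via tile-proportion
    statistics, and principal-component analysis for sequencing batch
    effects.  Results are written as a BGZF-compressed BED coverage matrix,
    an extended PED sample-QC table, and a self-contained HTML report with
    per-chromosome coverage tracks.  Includes a seeded synthetic-BAM
    generator and a per-base depth oracle so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    IRanges,
    data.table,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
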