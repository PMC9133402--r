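Package: spotTCR
Title: Spot-Resolved T Cell Receptor Clonotype Mapping for Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers spot-localized T cell receptor beta (TCRbeta)
    clonotypes from targeted enrichment of spatial gene-expression
    libraries and links them to single-cell-defined clone phenotypes.
    Provides spot barcode and UMI demultiplexing with one-mismatch
    whitelist correction, a lightweight V/J caller with CDR3 extraction
    for end-to-end testing, family-level clonotype identity with
    alpha-chain rescue, repertoire diversity and overlap statistics
    (Shannon, Morisita-Horn), bystander specificity filtering from
    IFN-gamma capture experiments, tumor-parenchyma localization and
    distance-to-border statistics with nonparametric tests, and a
    synthetic-data generator producing barcoded FASTQ reads with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
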