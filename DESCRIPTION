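Package: innateness
Title: Quantifying Lymphocyte Innateness from Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the transcriptional "innateness" of human
    lymphocyte populations. Implements per-gene association with a
    cell-type innateness rank gradient (linear mixed models with a donor
    random intercept and likelihood-ratio tests for bulk data; linear
    models with technical covariates for single cells), a PCA-loading
    innateness score projectable onto new samples or cells,
    hashing-antibody droplet demultiplexing with explicit quality-control
    criteria, minimal hypergeometric enrichment over effect-size-ranked
    gene lists, expression-matched pathway nulls, peak-to-gene target
    assignment with logistic target-enrichment tests, and ancillary
    metrics (individual innateness metric, gene-set expression mass, CFSE
    division index). Includes synthetic-data generators emulating the
    bulk, single-cell, and cohort study designs so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
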