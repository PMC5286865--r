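Package: arsiscan
Title: Repetitive-Substring Scoring of Regulatory Information in
    Coding and Non-Coding Regions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene-expression regulatory information directly from
    genomic sequence with the Average Repetitive Substring Index (ARSI):
    per-position longest-match profiles of a query against a reference set
    of genetic elements, leave-one-out scoring of 5'UTRs, ORFs, introns and
    3'UTRs, anchor-aligned sliding-window (metagene) profiles around ORF
    boundaries and splice sites, composition- and consensus-preserving
    randomized genomes with Z-score profiles, correlation of scores with
    mRNA levels and protein abundance, and a synthetic-genome generator
    with known motif placements and expression classes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: Sequencing, GeneExpression, MotifDiscovery, Transcription
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'arsiscan-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'arsi-core.R'
    'expression-stats.R'
    'sequence-io.R'
    'null-models.R'
    'profiles.R'
    'pipeline.R'
    'synthetic-data.R'
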