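Package: carforge
Title: Combinatorial CAR Signaling-Domain Libraries, Single-Cell CAR
    Demultiplexing and Pooled-Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing combinatorially shuffled chimeric antigen
    receptor (CAR) signaling-domain libraries by simulated Type IIS
    (Golden Gate) digestion and ligation, for assigning a CAR variant to
    each single-cell barcode from long-read amplicon sequencing
    (scCAR-seq), and for analysing pooled single-cell functional screens:
    quality control, log-normalization, subsampling, graph-based
    clustering with adjusted-Rand-index stability, detection of
    CAR-induced clusters, per-variant enrichment, pseudo-bulk
    aggregation, PCA, rank-based gene-set scoring and Wilcoxon rank-sum
    differential expression. Seeded synthetic-data generators for domain
    pools, barcoded long reads and negative-binomial count matrices make
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
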