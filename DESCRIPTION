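Package: cellmodelr
Title: Ranking Cancer Cell Lines as Tumour Models by Genomic Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well cancer cell lines model a tumour cohort by
    comparing genomic profiles. Computes fraction genome altered from
    segmented copy-number data, maps segments to gene-level copy number,
    measures copy-number concordance between each cell line and a tumour
    cohort (per-tumour correlations, their median, and correlation with the
    cohort mean profile), derives coverage-corrected mutation burden per
    megabase from MAF-style catalogues with per-base (wig) or per-exon
    coverage, flags hypermutator outliers, and combines these into a
    composite suitability score with a good/moderate/poor tiering. An
    expression module provides robust z-scoring, variable-gene selection,
    correlation-distance hierarchical clustering, PCA, expression-based
    cell-line ranking, and a Kendall rank-concordance test. A seeded
    synthetic-cohort generator emulates high-grade serous ovarian cancer
    tumours and ovarian cell-line panels so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
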