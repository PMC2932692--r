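Package: chiptile
Title: ChIP-Chip Tiling-Array Analysis of Gene-Body Chromatin Marks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for two-channel tiling-microarray ChIP
    (ChIP-chip) of chromatin factors and histone marks on a compact genome:
    z-score normalization of per-probe log2 ratios with optional
    anchored (reference-chromosome) rescaling, ChIPOTle-style sliding-window
    peak calling with a Gaussian null estimated from reflected negative
    scores and Bonferroni control, control-peak subtraction, peak-to-gene
    annotation with an exon/intron/3'/5'/distal summit hierarchy,
    chromosome-distribution statistics under a uniform-by-length null,
    metagene TSS/TES and exon-boundary profiles, expression-class gene-set
    statistics, and expression-array summarization (quantile normalization
    plus median polish). A synthetic-data generator emulates tiled log-ratio
    tracks with gene-body enrichment domains, replicate structure and an
    X-like chromosome depleted of germline-expressed genes, and provides a
    truth table for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
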