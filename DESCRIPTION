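Package: txatlas
Title: Chromosome-Scale Transcriptome Maps from FPKM Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds a transcriptome map of a chromosome from gene models and a
    multi-condition FPKM atlas. Classifies transcriptionally active regions
    (expressed genes, expressed pseudogenes, novel transcribed regions,
    putative lincRNAs, cis-natural antisense transcripts), types alternative
    splicing events (intron retention, exon skipping, alternative 5'/3'
    splice sites, mutually exclusive exons), relates expression level and
    breadth to gene structure through equal-size expression bins, partitions
    the chromosome with sliding-window density tracks and binary-segmentation
    changepoints, and detects co-expression clusters and gene islands
    (insulae). Ships a synthetic-chromosome generator with truth labels so
    that every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
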