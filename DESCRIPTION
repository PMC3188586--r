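Package: rnatoolbox
Title: Mapped-Read Analysis Toolbox for RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the downstream analysis of mapped high-throughput
    sequencing reads: an indexed genomic-interval engine using the nested-bin
    scheme, readers and writers for SAM, BED, GFF3 and generic tabular mapper
    output, read filtering, overlap selection against reference annotations,
    single-linkage read clustering (including bidirectional-promoter style
    strand patterns), Fisher exact-test differential expression with three
    count normalizations and false discovery rate control, distribution and
    meta-gene profile computations, and a worked small-RNA (piRNA) cluster
    discovery pipeline. A deterministic synthetic-data generator produces
    mapped reads with planted cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
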