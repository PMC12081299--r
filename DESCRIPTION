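Package: trnlink
Title: Enhancer-Promoter Linking and State-Specific Regulatory Networks
    from Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing state-specific transcriptional
    regulatory networks from paired single-nucleus RNA and ATAC data.
    Builds metacells by k-nearest-neighbour aggregation in a co-embedding,
    links enhancers to promoters by per-gene linear regression of metacell
    expression on the accessibility of peaks within +/-500 kb of the
    transcription start site, and assembles transcription-factor/target
    networks gated by motif presence, differential accessibility and
    differential expression. Also provides the surrounding analysis steps:
    quality-control filters, log normalization, Gini-index gene filtering,
    500-bp peak merging, chromVAR-style motif deviation z-scores,
    one-vs-rest differential expression with fraction filters, pseudo-bulk
    differential accessibility, signature scoring with matched control
    genes, patient stratification rules, spatial neighborhood statistics
    on segmented cell tables, and paired composition-shift tests. A
    synthetic multiome/spatial/cohort generator with planted ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    readr,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
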