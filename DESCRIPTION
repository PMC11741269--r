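Package: crmscape
Title: Temporal Peak Dynamics, Super-Enhancer Calling and Expression
    Robustness for Early-Embryo Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative toolkit for dissecting transcription-factor
    driven cis-regulation in early embryos. Classifies stage-resolved
    ChIP-seq peaks into temporal occupancy classes, calls regions
    co-occupied by two transcription factors and a coactivator,
    identifies super-enhancers by rank-ordering stitched enhancer loci
    and cutting at the signal curve's inflection, calls direct target
    genes from morphant (knockdown) differential expression combined
    with binding-site proximity, profiles position-weight-matrix motif
    density around peak summits, and quantifies single-nucleus
    expression robustness (cluster z-scores and coefficient of
    variation). Ships deterministic seeded generators that emit every
    input format with planted ground truth, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
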