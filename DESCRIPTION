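Package: ldgraph
Title: Decomposable Graphical Models for Fine-Scale Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates chromosome-wide, fine-scale linkage-disequilibrium
    structure from SNP data as decomposable (chordal) graphical models.
    Provides the standard greedy forward-backward search that minimizes a
    penalized likelihood criterion (BIC or AIC) starting from the serial
    "skeleton" of physically adjacent markers, and a fast linear-time
    blockwise variant that fits overlapping marginal models and stitches
    them together before triangulating with maximum cardinality search.
    Includes interval height/width complexity profiles, sliding-window
    haplotype entropy, sample trees, pairwise r-squared matrices,
    simulation from fitted models via the junction forest, edgewise
    graph-recovery rates, and LD-graph layout and plotting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    withr
Config/testthat/edition: 3
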