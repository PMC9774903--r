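Package: multitissue
Title: Housekeeping Genes, Tissue-Specific Genes and Co-Expression
    Modules from Multi-Tissue Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq expression matrices (FPKM)
    spanning many tissues. Profiles per-tissue gene activity, detects
    housekeeping genes and tiers them by coefficient of variation and
    expression level, detects tissue-specific genes by a three-criterion
    rule with a single-tissue refinement, builds a weighted gene
    co-expression network (soft-thresholded adjacency, topological
    overlap, average-linkage modules, eigengenes, module-tissue
    association, hub-gene calling), and runs hypergeometric
    over-representation tests against user-supplied gene sets. Includes a
    synthetic-data generator with planted ground truth so every stage can
    be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
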