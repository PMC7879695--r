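Package: lncnet
Title: LncRNA-mRNA Co-Expression and Regulation Network Analysis for
    Two-Group Expression Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative lncRNA-mRNA analysis pipeline for two-group
    expression microarray studies: quantile normalization and log2
    transformation of raw intensities, two-group differential expression
    with a fold-change and Student's t filter, Pearson co-expression
    screening of differentially expressed lncRNA-mRNA pairs, genomic
    cis/trans classification of significant pairs by a 300 kb distance
    window, trans-network construction with maximum-neighborhood-component
    hub scoring, and local hypergeometric over-representation analysis
    against user-supplied gene-set collections. Includes a seeded
    synthetic-data generator that plants known differential-expression
    effects, lncRNA-mRNA correlation structure, and cis/trans locus
    geometry for recovery testing, and a single-configuration pipeline
    driver with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
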