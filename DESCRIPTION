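Package: lncoex
Title: Differential lncRNA-mRNA Coexpression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression and differential coexpression analysis
    of long non-coding RNAs and mRNAs between two tumor cohorts and a normal
    reference. Implements TMM/CPM normalization and moderated-t differential
    expression, per-cohort hard-threshold Pearson coexpression networks with
    clustering-coefficient-based threshold selection under a scale-free
    constraint, cohort-difference networks with connected-component census
    and lncRNA-mRNA / antisense pair extraction, hypergeometric pathway
    over-representation, and median-split Kaplan-Meier / log-rank / Cox
    survival analysis. Includes a negative-binomial synthetic-data generator
    with planted differential expression, planted coexpression modules and
    planted hazard effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    limma,
    edgeR,
    igraph,
    survival,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
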