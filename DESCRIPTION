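Package: srsomics
Title: Sepsis Response Signature Discovery, eQTL Mapping, and Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated transcriptomic and genetic analysis of the host
    response in sepsis. Discovers sepsis response signature (SRS) patient
    groups from blood leucocyte expression by hierarchical clustering with
    k-means consolidation, performs empirical-Bayes moderated-t differential
    expression, builds a sparse gene classifier with leave-one-out
    cross-validation, tests directional gene signatures by rotation, maps
    cis/trans expression quantitative trait loci (eQTL) with principal
    component covariates and SRS-specific calling, tests enrichment of lead
    eSNPs in epigenetic-mark intervals, and relates SRS membership to
    survival. A seeded synthetic cohort generator emulating the study's
    statistical structure supplies ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    glmnet,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
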