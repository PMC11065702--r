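Package: stimsig
Title: Interaction Signatures and Gene Modules for Multi-Genotype Immune
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis of multi-genotype immune
    transcriptomes under homeostatic, context-deprived and stimulated
    conditions. Provides TMM/voom-style count normalization, per-gene
    weighted linear models with an optional random intercept for the
    experiment identifier, a five-signature classifier of stimulation x
    mutant interaction effects, replicate-correlation sample QC with a
    keep-top-three rescue rule, effect-profile gene-module discovery by
    random-walk community detection on a k-nearest-neighbour graph,
    contrast-similarity multidimensional scaling, and enrichment statistics
    (Fisher's exact, preranked running-sum, CERNO rank test, and a
    random-sampling overlap test). A negative-binomial count simulator with
    planted effect archetypes makes the full pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    igraph,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
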