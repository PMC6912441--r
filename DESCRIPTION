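Package: surprisal
Title: Surprisal Analysis of Bulk Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decomposes log-scale gene expression matrices into a balanced
    state plus thermodynamic-style constraints via singular value
    decomposition, computes per-sample Lagrange multipliers with propagated
    upper-bound error bars, ranks genes by constraint weight, and scores
    gene-set enrichment with the set-ratio statistic. Ships a synthetic-data
    generator emulating a batch-culture concentration-by-time design with
    biological replicates, so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Transcriptomics, GeneExpression, DimensionReduction,
    GeneSetEnrichment, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
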