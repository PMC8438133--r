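Package: germnet
Title: Module-Network Gene Regulatory Network Inference for Germinating
    Seed Time-Series RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative time-series transcriptome analysis pipeline for
    germinating low- versus normal-phytic-acid seeds. Provides negative
    binomial Wald differential expression with median-of-ratios
    normalization and a variance-stabilizing transform, Gaussian
    finite-mixture co-expression module discovery with BIC model selection,
    hypergeometric GO term enrichment with Benjamini-Hochberg FDR control,
    module-network gene regulatory network inference by an ensemble of five
    algorithms (ARACNE, CLR, LARS, shrinkage partial correlation, random
    forest importance) with at-least-four-of-five consensus voting,
    TF-to-gene edge expansion with cross-species DAP-seq and motif
    validation, and a synthetic count generator with planted ground truth
    (differential genes, modules, TF-module regulation) for end-to-end
    benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
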