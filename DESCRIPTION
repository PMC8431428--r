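Package: triadex
Title: Hybrid-Parent Triad Expression Patterns and Heterosis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene expression inheritance in
    (female parent, male parent, F1 hybrid) triads from bulk RNA-seq count
    matrices. Provides a self-contained negative-binomial Wald test for
    pairwise differential expression (median-of-ratios normalisation,
    method-of-moments dispersion, Benjamini-Hochberg adjustment), the
    twelve-class inheritance-mode classifier separating additive,
    expression-level dominant and overdominant genes, phenotypic mid-parent
    and high-parent heterosis statistics with ANOVA and Tukey HSD letter
    displays, hypergeometric over-representation analysis, qPCR 2^-ddCt
    relative quantification with RNA-seq concordance checks, and a
    negative-binomial triad simulator with planted inheritance modes that
    serves as ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
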