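Package: panelprofiler
Title: Expression Profiling of Disease Gene Panels Across Candidate Cell
    Culture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative expression profiling of a disease gene panel across
    candidate cell culture models. Normalizes gene-level read counts to RPKM
    and TPM, applies a detection floor, classifies each panel gene by its
    highest-expressing cell type, and summarizes assignment counts overall
    and per disease group. Scores pathway-level coverage of gene sets above
    an expression threshold, quantifies similarity of bulk samples to
    single-cell reference profiles by Spearman correlation with a rank-sum
    test against the pooled background of all comparisons, and analyzes
    qPCR plates by delta-delta-CT with one-way ANOVA. Ships a negative
    binomial count simulator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
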