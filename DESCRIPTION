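Package: septiclass
Title: LogitBoost Diagnostic Classification for Multi-Gene Sepsis Expression Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating multi-gene transcriptional
    diagnostics that separate sepsis from non-infectious systemic inflammation.
    Implements efficiency-corrected relative quantification of real-time PCR
    amplification curves (second-derivative-maximum take-off cycles, Pfaffl
    ratios, multi-reference-gene normalization with plate-level QC), marker
    screening (signal/fold-change filters, moderated t statistics with Holm
    adjustment), a from-scratch binary LogitBoost classifier over decision
    stumps whose posterior probabilities serve as a diagnostic index, and a
    validation harness with repeated stratified random partitioning, a
    label-permutation null with empirical p-values, leave-one-out
    cross-validation and PCA projections. A synthetic three-cohort study
    generator provides statistically controlled fixtures for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caTools,
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, GeneExpression, qPCR, ImmunoOncology
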