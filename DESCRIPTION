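Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR Ct Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ranking candidate reference (housekeeping) genes from
    RT-qPCR threshold-cycle (Ct) tables. Implements the comparative delta-Ct
    method, geNorm (M values, stepwise exclusion, normalization factors,
    pairwise-variation series and the optimal-gene-number rule), a model-based
    NormFinder-style variance decomposition with empirical-Bayes shrinkage,
    BestKeeper descriptive statistics, and RefFinder-style aggregation of
    method ranks by geometric mean, together with amplification-efficiency
    estimation from dilution series, cross-condition rank averaging with
    exclusion sensitivity, and a seeded synthetic Ct-table generator with
    known ground-truth stability ordering.
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
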