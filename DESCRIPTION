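Package: caninests
Title: Cross-Species Comparative Analysis of Canine Soft Tissue Sarcoma
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing canine soft tissue sarcoma gene expression
    (NanoString-style count panels) with human sarcoma subtypes. Implements
    pooled-distribution quantile normalization, geNorm housekeeping-gene
    stability selection and normalization, per-gene ANOVA screening with
    hierarchical clustering, rank-based cross-species subtype similarity with
    permutation and bootstrap inference, Kaplan-Meier and log-rank survival
    comparisons, Wilcoxon rank-sum tests, and five-field immunohistochemistry
    grading. Includes a negative-binomial cohort simulator (counts, clinical
    endpoints, IHC field counts) so the full pipeline can be exercised and
    validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
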