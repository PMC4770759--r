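Package: cnamlsig
Title: Prognostic mRNA Expression Signatures for Cytogenetically Normal AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation machinery for small prognostic
    gene-expression signatures in cytogenetically normal acute myeloid
    leukemia. Implements the full workflow: microarray-style preprocessing
    (log2 transform, quantile normalization, coefficient-of-variation probe
    collapsing, per-probe z-standardization), two-stage signature selection
    (induction-response differential expression followed by univariate Cox
    survival filtering), an equal-weight z-score risk score with median and
    mean +/- 1 SD groupings, Kaplan-Meier / log-rank / proportional-hazards
    survival analysis with transplant censoring, a random-gene-set
    permutation test of the scoring system's non-randomness, a GSEA-style
    running-sum enrichment analysis with gene permutation, and 2x2
    association statistics for clinical and mutation covariates. A seeded
    synthetic-cohort generator with a planted co-expressed signature
    provides ground truth for calibration and recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
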