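Package: cuproscore
Title: Cuproptosis Subtyping and Scoring for Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a reusable pipeline for copper-death (cuproptosis)
    molecular subtyping of bulk expression cohorts: cohort merging with
    FPKM-to-TPM conversion, parametric empirical-Bayes batch correction,
    resampled consensus clustering with a k-medoids inner clusterer and PAC
    model selection, single-sample gene-set enrichment (ssGSEA) immune
    landscape scoring, moderated-t differential expression with
    over-representation analysis, univariate Cox screening, shadow-feature
    (Boruta-style) selection with principal-component signature scores
    combined into a per-sample cuproptosis score (CUS), survival
    stratification at a maximally selected log-rank cutpoint, and
    ridge-regression drug-sensitivity imputation from a reference panel.
    Ships a seeded synthetic-cohort generator with known ground truth so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    limma,
    sva
Config/testthat/edition: 3
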