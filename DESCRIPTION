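Package: proteodx
Title: Integrated Proteome and Targeted-RNA Diagnostics for Inborn Errors of
    Immunity
Version: 0.1.0
Authors@R:
    person("proteodx", "developers", email = "proteodx@example.org",
           role = c("aut", "cre"))
Description: Missing-value-aware analysis of PBMC protein intensity matrices
    integrated with targeted RNA sequencing counts for single-case genetic
    diagnosis of inborn errors of immunity. Provides left-censored
    missing-value diagnostics and filtering, zero / minimum-deterministic
    imputation, quantile and robust-linear-regression normalization, a
    variance-stabilizing count transform, cohort z-score disease-gene
    calling with archetype classification, per-gene protein-mRNA Spearman
    correlation profiling, marker-based k-means immunophenotype clustering,
    moderated differential expression with hypergeometric gene-set
    enrichment, and a synthetic cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
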