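Package: oncodep
Title: Oncogene Dependency Mapping from Isogenic Pooled CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for isogenic pooled CRISPR knockout
    screens aimed at mapping oncogene-specific genetic dependencies.
    Provides guide-level quality control (read-per-million abundance
    filtering, cross-targeting guide exclusion, replicate correlation,
    robust SSMD), anchored CRISPR-score normalization against reference
    essential and nonessential gene sets, gene-level significance by
    alpha-robust-rank-aggregation with a permutation null, cross-line
    dependency classification (pan-essential, oncogene dependency,
    baseline synthetic lethal, cooperating knockout) with Venn
    partitioning, differential drug sensitivity via logistic
    dose-response fits and median-centered delta-AUC, and a tumor-cohort
    alteration/low-expression co-occurrence analysis with a one-sided
    Fisher exact test. Includes synthetic-data generators for screens,
    dose-response plates and tumor cohorts so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
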