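Package: srmstage
Title: Targeted SRM-MS Quantification and Staging of CSF Alzheimer's Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for targeted selected-reaction-monitoring (SRM) mass
    spectrometry quantification of cerebrospinal-fluid peptide biomarkers with
    stable-isotope-dilution light/heavy standards. Converts transition-level
    chromatogram areas into light/heavy total-area ratios, applies ratio
    dot-product co-elution and coefficient-of-variation quality gates from
    pooled reference standards, and carries the gated log2 ratio matrix
    through differential abundance (one-way ANOVA with Tukey post hoc tests,
    Welch t-tests with Benjamini-Hochberg correction), biomarker stage
    classification (early, progressive, reversing), immunoassay trait
    correlation, and per-peptide ROC diagnostics with DeLong confidence
    intervals and stratified cross-validated AUC. A synthetic-cohort
    generator emulating a three-group Alzheimer's disease study (control,
    asymptomatic, symptomatic) plus QC pools, isotopologue dilution ladders,
    APOE allele-specific peptides, and blood-contamination spikes makes the
    full pipeline runnable and testable without any instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
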