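---
title: "Quantifying and staging CSF biomarkers from targeted SRM measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and staging CSF biomarkers from targeted SRM measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmstage)
library(dplyr)
```

## The measurement model

In a scheduled selected-reaction-monitoring (SRM) assay, each tryptic
peptide is monitored through three precursor-to-fragment transitions, in
two isotopic forms: the endogenous *light* peptide and a synthetic *heavy*
standard carrying a ^13^C/^15^N-labelled C-terminal lysine or arginine.
Light and heavy forms co-elute, so the heavy standard acts as an internal
reference in every injection. The quantity carried through all downstream
analysis is the **total area ratio**

$$ R \;=\; \frac{\sum_{k=1}^{3} L_k}{\sum_{k=1}^{3} H_k}, $$

the summed light transition areas over the summed heavy areas
(`total_area_ratio()`). A zero light sum is a valid measurement — the
APOE2-specific peptide is genuinely absent from samples without an ε2
allele — whereas a zero heavy sum indicates assay failure, because the
standard is always spiked.

Two quality metrics guard this ratio:

* the **ratio dot product** (`ratio_dot_product()`), the cosine of the
  light and heavy 3-vectors of transition areas. It is 1 exactly when the
  two profiles are proportional (clean co-elution) and drops when an
  interfering signal distorts one label's profile. We use the cosine as
  the reference formula; the metric is scale-invariant in each argument.
* the **coefficient of variation** of the ratio across replicate
  injections of pooled reference CSF (`summarize_qc()`), computed on raw
  ratios with the sample (n − 1) standard deviation. Computing CV on raw
  rather than log ratios matches the convention of deposited QC tables.

`apply_gates()` retains a peptide when its CV is at or below 20% in **at
least one** of the two QC pools *and* its mean ratio dot product is at
least 0.90 in **both** pools. The 20% boundary is inclusive (a peptide at
exactly CV = 20% is kept): the removal rule is stated as "CV > 20%" while
the retention criterion is "CV < 20%", and we resolve the ambiguity at the
boundary in favour of retention, documented here.

Peak integration (`integrate_trace()`) is a trapezoidal integral above a
constant baseline set to the minimum intensity inside the integration
window. Interactive peak-boundary editing is deliberately replaced by this
fixed automatic rule; interference that such editing would have caught is
instead caught by the ratio dot-product gate. A retention-time check
(apex within ±0.2 min of schedule) is available as a flag but no numeric
tolerance is asserted beyond that configurable default.

Before statistics, zeros (APOE allele-specific absences) are imputed as
one-half of the row's minimum nonzero ratio (`impute_zeros()`), and the
matrix is log2-transformed (`log2_matrix()`), which refuses non-positive
entries rather than silently dropping them.

## The synthetic cohort generator

Every stage of the pipeline is exercised by a generator
(`generate_cohort()`, `generate_qc_pools()`, `render_traces()`,
`generate_dilution_series()`) whose defaults are the study conditions the
analysis assumes:

* **Cohort:** 133 Control, 127 AsymAD (cognitively normal,
  biomarker-positive) and 130 AD samples; 15 replicate injections of each
  of two pooled QC standards (AT− and AT+).
* **Panel:** 62 light/heavy peptide pairs — 54 biomarker peptides, two
  albumin and two hemoglobin peptides monitored for blood contamination,
  and the four APOE allele-specific peptides CLAVYQAGAR (E2), LGADMEDVR
  (E4), LGADMEDVCGR (E2/E3) and LAVYQAGAR (E3/E4).
* **Noise law:** the measured ratio is the true ratio times a mean-1
  lognormal factor with CV 12% (the study-level replicate precision);
  each of the six transition areas then receives independent mean-1
  lognormal noise at 5%. The distributional form is an assumption of the
  generator, recorded here, not a reported property of CSF.
* **Heavy standard:** a constant total area of 10^5^ per peptide with 2%
  injection jitter, reflecting a fixed spike volume per digest.
* **Effects:** changing peptides carry log2 group effects of magnitude
  0.7 by default, arranged in the four trajectory archetypes — *early*
  (AsymAD = AD = +0.7), *progressive* (+0.35 then +0.7), *reversing*
  (+0.7 in AsymAD, back to 0 in AD) and *unchanged*. The QC pools use a
  separate AT+ vs AT− effect vector with 21 peptides up and 10 down.
  0.7 log2 units (a 1.6-fold change) is a typical magnitude for the
  strongly changed CSF markers in this panel; it is chosen once as the
  default study condition, with the magnitude exposed as a parameter.
* **Traits:** MoCA, Aβ~42~, tTau and pTau are drawn per group from the
  cohort-characteristic means and SDs (e.g. pTau 14.7 ± 3.2 / 25.2 ± 11.1
  / 38.5 ± 15.5 pg/mL), truncated at plausibility bounds; the amyloid
  immunoassay saturates at 1,700 pg/mL, so control-like samples
  accumulate at exactly 1,700 as in the real assay. SMOC1 and YWHAZ
  measurement noise is correlated with tTau's within-group variation at
  ρ = 0.5 by default so that trait-correlation analyses have signal.
* **APOE:** genotypes are drawn from typical clinical-cohort frequencies
  (E3/E3 0.55, E3/E4 0.22, E2/E3 0.10, E4/E4 0.08, E2/E4 0.03, E2/E2
  0.02); an allele-specific peptide's ratio scales linearly with allele
  dosage (0/1/2), with no attempt to model true isoform stoichiometry.
* **Contamination:** 2% of samples have their hemoglobin peptide ratios
  multiplied 10-fold, with truth flags returned for benchmarking the
  robust-z flagging rule.

Deterministic behaviour under a seed is part of the contract: identical
seeds give bit-identical cohorts, pools, ladders and traces.

### What the generator does *not* emulate

Between-subject biological variance beyond the trait coupling is not
modelled: all within-group spread comes from the 12% measurement CV. Real
CSF cohorts have large biological spread, so synthetic ROC curves for
effect-carrying peptides are far stronger (AUC ≈ 1 at effect 0.7) than
the 0.70–0.90 AUCs typical of real cohorts. Passing tests therefore
demonstrate correctness of the computations and recoverability of known
truth — not realistic effect-size/AUC relationships. Chromatographic
drift, carry-over and plate/batch effects are also out of scope (the
emulated study randomises acquisition order and does not model them).

## Differential abundance and staging

`anova_tukey()` fits a one-way ANOVA of log2 ratio on diagnosis group per
peptide and reports Tukey honest-significant-difference adjusted p-values
from the studentized-range distribution for the three pairwise
comparisons, alongside the overall F test. `ttest_bh()` runs Welch
(unequal-variance) t-tests — "t test" alone underdetermines the variant,
and Welch is the safer default — with Benjamini–Hochberg correction
across the peptide family. When both groups are exactly constant, p is
reported as 1 if the constants agree and 0 if they differ; there is no
sampling variability to quantify in either degenerate case. A peptide
with zero variance overall reports F = 0 and p = 1.

`classify_stage()` applies the trajectory rule on Tukey-adjusted p-values
at α = 0.05 (the post-hoc values, not the raw pairwise p — volcano-style
outputs expose both, classification uses Tukey):

| AsymAD vs Control | AD vs AsymAD | category |
|---|---|---|
| significant | not significant | early |
| significant | significant, same sign | progressive |
| significant up | significant down | reversing |
| none of the three significant | | unchanged |
| anything else | | other |

Albumin, hemoglobin and APOE allele-specific peptides are excluded from
volcano/staging analyses by their panel role (`panel_analysis_peptides()`):
they are monitored for sample integrity and genotyping, not as disease
biomarkers.

`pearson_panel()` correlates each peptide with each trait (Pearson r,
Student t p, n of pairs); samples at the 1,700 pg/mL amyloid saturation
ceiling are excluded from amyloid-involving traits only (amyloid itself
and tTau/Aβ), never from MoCA or tau correlations. Blood-contamination
flags (`flag_blood_contamination()`, robust z of log2 hemoglobin ratios,
threshold 3) are annotations only — no statistic auto-excludes flagged
samples, matching the reporting-without-correction practice.

## ROC diagnostics

`roc_single()` computes the AUC as the Mann–Whitney rank statistic with
ties counted one half. For a single predictor this is mathematically
identical to the AUC of a binomial-GLM fit, because the fitted score is a
monotone transform of the predictor; the rank route avoids convergence
edge cases under perfect separation, and the equivalence to exhaustive
pair counting is asserted in the test suite. The predictor is
auto-oriented so the reported AUC is at least 0.5, with the direction
recorded. Confidence intervals and the p-value against AUC = 0.5 use the
DeLong placement variance. The reported sensitivity/specificity/accuracy
sit at the Youden-optimal cutoff, with ties at equal J broken toward
higher specificity. The accompanying p-value is the DeLong test against
AUC = 0.5, the presumed meaning of the "p" column in ROC statistic
tables of this kind.

`cv_auc()` builds outcome-stratified folds by per-class round-robin
assignment after a seeded shuffle, fits the single-predictor binomial GLM
on each training split, pools the out-of-fold linear predictors, and
reports the rank AUC of the pooled predictions with a DeLong interval.

**A known limitation:** for a peptide whose true effect is (near) zero,
the cross-validated AUC centres at 0.5 while the full-data AUC has
sampling standard deviation ≈ 3.5 percentage points at n = 263 (and its
auto-oriented version is biased upward by about 2.8 points). The two
statistics decorrelate, so the expected |full − cv| gap for a null
predictor is several percentage points *regardless of implementation* —
we verified this for pooled-score, fold-averaged, oriented and unoriented
variants. Cross-validated and full-data AUC agree to within about one
percentage point only for predictors that carry genuine signal (here,
log2 effects of roughly 0.2 and above at the default noise); that is the
regime in which the agreement property should be read.

`rank_top()` orders ROC results by descending AUC, breaking ties by
narrower DeLong interval and then peptide id.

## Instrument-performance analytics

The isotopologue dilution ladder (six peptides at 1 pmol, 100 fmol,
10 fmol, 1 fmol, 100 amol) probes sensitivity and dynamic range.
`labelfree_cv_by_level()` computes per-level raw-area CVs, calling a
level *not detected* when its mean raw area is at or below the noise
floor — the operational rule behind "ND" is an implementation convention
of this package, since only the outcome is conventionally reported.
`estimate_lod()` takes the LOD as the lowest detected rung with CV at or
below 20%, the dynamic range as log10(max/min) over detected rungs, and
linearity as the slope/R² of log10(area) on log10(amount). Under the
default generator the LOD lands on the 1–10 fmol rungs with the 100-amol
rung undetected and log–log slope within [0.9, 1.1].

`call_apoe()` converts the four allele-specific peptide ratios to
presence bits at a *relative* threshold — 5% of the peptide's cohort
median among nonzero measurements — because absolute intensity scales
differ between synthetic and real data; the bit pattern is mapped through
the six-genotype truth table, with unmatched patterns reported as
indeterminate rather than forced. A dosage score (heterozygous carriage
sits near half the homozygous median) is reported as corroboration but
never overrides the presence pattern.

## Numerical and design choices

* CSV dialect: comma-separated, UTF-8, "." decimal; ratios serialised at
  6 significant digits; empty cells are missing trait markers, zeros are
  biological absences; sample column headers are treated as opaque
  unique ids, so any naming scheme round-trips.
* Degenerate inputs fail loudly: all-zero peptide rows cannot be imputed,
  non-positive entries cannot be logged, a zero-norm transition vector
  has an undefined (NA) ratio dot product distinct from 0, a missing
  heavy spike is an error rather than an infinite ratio.
* Gate monotonicity holds by construction: raising the CV gate can only
  grow the accepted set.
* Problem sizes in the test suite were chosen to keep the full run at a
  few minutes on one core: 50 replicate cohorts at full design for error
  rates, power and stage recovery; 20 seeds for contamination flagging;
  200 resamples for null distributions; 400 bootstrap draws for the
  DeLong cross-check.

## Worked pipeline

```{r pipeline, eval = FALSE}
design <- cohort_design()

# assay qualification on pooled QC standards
qc <- generate_qc_pools(design, seed = 7)
gates <- apply_gates(summarize_qc(qc$quants))

# cohort analysis on the gated panel
cohort <- generate_cohort(design, seed = 7)
l2 <- cohort$ratios |> impute_zeros() |> log2_matrix()
diff <- anova_tukey(l2, cohort$meta)
stages <- classify_stage(diff, peptides = panel_analysis_peptides(design$panel))
rocs <- roc_panel(l2, cohort$meta, "AD", "Control",
                  peptides = panel_analysis_peptides(design$panel))
rank_top(rocs, top_k = 5)
```
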