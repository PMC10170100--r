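# Differential abundance and staging over the log2 ratio matrix: one-way
# ANOVA with Tukey post hoc tests across the three diagnosis groups, Welch
# t-tests with Benjamini-Hochberg correction for two-group comparisons,
# the early/progressive/reversing stage rule, and trait correlations.

comparison_label <- function(case, control) {
  abbr <- function(g) if (g == "Control") "CT" else g
  paste0(abbr(case), "_vs_", abbr(control))
}

join_long <- function(log2_mat, meta, peptides = NULL) {
  assert <- c("sample_id", "condition")
  if (!all(assert %in% names(meta))) abort("`meta` needs sample_id and condition columns.")
  long <- ratio_long(log2_mat) |>
    inner_join(meta[, c("sample_id", "condition")], by = "sample_id")
  if (!is.null(peptides)) long <- long[long$peptide_id %in% peptides, ]
  long
}

#' One-way ANOVA with Tukey post hoc tests per peptide
#'
#' Fits a one-way ANOVA of log2 ratio on diagnosis group for each peptide
#' and reports, for each pairwise comparison, the difference of group means
#' (log2 fold change) and the Tukey honest-significant-difference adjusted
#' p-value from the studentized-range distribution, alongside the overall
#' F-test p-value.
#'
#' @param log2_mat Log2 ratio matrix tibble (`peptide_id` + sample columns).
#' @param meta Sample metadata with `sample_id` and `condition`.
#' @param groups The (ordered) group labels to include; default the three
#'   diagnosis groups.
#' @param peptides Optional subset of peptide ids to analyse.
#' @return Tibble: `peptide_id`, `comparison` (e.g. `"AsymAD_vs_CT"`),
#'   `log2fc`, `tukey_p`, `p_anova`, `f_stat`.
#' @export
anova_tukey <- function(log2_mat, meta,
                        groups = c("Control", "AsymAD", "AD"),
                        peptides = NULL) {
  long <- join_long(log2_mat, meta, peptides)
  long <- long[long$condition %in% groups, ]
  long$condition <- factor(long$condition, levels = groups)
  counts <- table(long$condition[long$peptide_id == long$peptide_id[1]])
  if (any(counts < 2)) abort("Every group needs at least 2 observations.")

  pair_names <- utils::combn(groups, 2, function(p) paste(p[2], p[1], sep = "-"))
  pairs <- utils::combn(levels(long$condition), 2, simplify = FALSE)
  purrr::map_dfr(split(long, long$peptide_id), function(df) {
    if (stats::sd(df$value) == 0) {
      # no variation at all: no evidence of any difference
      return(tibble(
        peptide_id = df$peptide_id[1],
        comparison = vapply(pairs, function(p) comparison_label(p[2], p[1]),
                            character(1)),
        log2fc = 0, tukey_p = 1, p_anova = 1, f_stat = 0
      ))
    }
    fit <- stats::aov(value ~ condition, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$condition
    tibble(
      peptide_id = df$peptide_id[1],
      comparison = vapply(strsplit(rownames(tk), "-", fixed = TRUE),
                          function(p) comparison_label(p[1], p[2]), character(1)),
      log2fc = unname(tk[, "diff"]),
      tukey_p = unname(tk[, "p adj"]),
      p_anova = an[["Pr(>F)"]][1],
      f_stat = an[["F value"]][1]
    )
  })
}

#' Welch t-tests with Benjamini-Hochberg FDR per peptide
#'
#' Two-group comparison of log2 ratios for every peptide with an
#' unequal-variance (Welch) t-test, corrected across the peptide family by
#' Benjamini-Hochberg. Degenerate rows where both groups are constant are
#' reported with p = 1 when the constants are equal and p = 0 when they
#' differ (there is no sampling uncertainty to quantify in either case).
#'
#' @param log2_mat Log2 ratio matrix tibble.
#' @param meta Sample metadata with `sample_id` and `condition`.
#' @param case,control Condition labels; `log2fc` is case minus control.
#' @param peptides Optional subset of peptide ids.
#' @return Tibble: `peptide_id`, `comparison`, `log2fc`, `t_p`, `bh_fdr`.
#' @export
ttest_bh <- function(log2_mat, meta, case, control, peptides = NULL) {
  long <- join_long(log2_mat, meta, peptides)
  long <- long[long$condition %in% c(case, control), ]
  res <- purrr::map_dfr(split(long, long$peptide_id), function(df) {
    x <- df$value[df$condition == case]
    y <- df$value[df$condition == control]
    if (length(x) < 2 || length(y) < 2) abort("Each group needs at least 2 observations.")
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    tibble(peptide_id = df$peptide_id[1],
           comparison = comparison_label(case, control),
           log2fc = mean(x) - mean(y),
           t_p = p)
  })
  res$bh_fdr <- stats::p.adjust(res$t_p, method = "BH")
  res
}

#' Classify peptides as early, progressive or reversing biomarkers
#'
#' Applies the stage rule to the Tukey results of the three pairwise
#' diagnosis comparisons, using adjusted p < `alpha` as significance:
#' \describe{
#'   \item{early}{significant in AsymAD vs Control but not AD vs AsymAD;}
#'   \item{progressive}{significant in both with the same direction
#'     (stepwise change from Control to AsymAD to AD);}
#'   \item{reversing}{significantly up in AsymAD vs Control and
#'     significantly down in AD vs AsymAD;}
#'   \item{unchanged}{no significant comparison at all;}
#'   \item{other}{any remaining pattern.}
#' }
#' Also returns per-comparison significant counts and the Venn intersection
#' counts of the three significant sets.
#'
#' @param diff Output of [anova_tukey()] for the three diagnosis groups.
#' @param alpha Significance threshold on the Tukey-adjusted p-values.
#' @param peptides Optional subset (typically [panel_analysis_peptides()],
#'   excluding albumin/hemoglobin/APOE monitoring peptides).
#' @return List of class `stage_result`: `calls` (tibble `peptide_id`,
#'   `category` and the supporting significance/direction columns),
#'   `sig_counts`, and `venn` (counts per intersection region).
#' @export
classify_stage <- function(diff, alpha = 0.05, peptides = NULL) {
  if (!is.null(peptides)) diff <- diff[diff$peptide_id %in% peptides, ]
  need <- c("AsymAD_vs_CT", "AD_vs_AsymAD", "AD_vs_CT")
  wide <- diff |>
    select("peptide_id", "comparison", "log2fc", "tukey_p") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("log2fc", "tukey_p"))
  if (!all(paste0("tukey_p_", need) %in% names(wide))) {
    abort("classify_stage() needs Tukey results for all three pairwise comparisons.")
  }
  sa <- wide$tukey_p_AsymAD_vs_CT < alpha
  sb <- wide$tukey_p_AD_vs_AsymAD < alpha
  sc <- wide$tukey_p_AD_vs_CT < alpha
  da <- wide$log2fc_AsymAD_vs_CT
  db <- wide$log2fc_AD_vs_AsymAD
  category <- dplyr::case_when(
    sa & !sb ~ "early",
    sa & sb & sign(da) == sign(db) ~ "progressive",
    sa & sb & da > 0 & db < 0 ~ "reversing",
    !sa & !sb & !sc ~ "unchanged",
    TRUE ~ "other"
  )
  calls <- tibble(
    peptide_id = wide$peptide_id, category = category,
    sig_asymad_ct = sa, sig_ad_asymad = sb, sig_ad_ct = sc,
    dir_asymad_ct = sign(da), dir_ad_asymad = sign(db)
  )
  sig_counts <- tibble(comparison = need, n_significant = c(sum(sa), sum(sb), sum(sc)))
  venn <- tibble(
    region = c("AsymAD_vs_CT_only", "AD_vs_AsymAD_only", "AD_vs_CT_only",
               "AsymAD_vs_CT&AD_vs_AsymAD", "AsymAD_vs_CT&AD_vs_CT",
               "AD_vs_AsymAD&AD_vs_CT", "all_three"),
    count = c(sum(sa & !sb & !sc), sum(!sa & sb & !sc), sum(!sa & !sb & sc),
              sum(sa & sb & !sc), sum(sa & !sb & sc), sum(!sa & sb & sc),
              sum(sa & sb & sc))
  )
  out <- list(calls = calls, sig_counts = sig_counts, venn = venn)
  class(out) <- "stage_result"
  out
}

#' Pearson correlations of peptides to immunoassay and cognition traits
#'
#' Correlates each peptide's log2 ratios with each trait across samples,
#' reporting Pearson's r, the Student t p-value and the number of paired
#' observations. Samples whose amyloid immunoassay value sits exactly at
#' the assay saturation maximum are excluded from amyloid-involving traits
#' (amyloid itself and the tTau/amyloid ratio) only.
#'
#' @param log2_mat Log2 ratio matrix tibble.
#' @param meta Sample metadata carrying the trait columns.
#' @param traits Trait column names to correlate.
#' @param saturation_value Amyloid assay ceiling (pg/mL).
#' @param peptides Optional subset of peptide ids.
#' @return Tibble: `peptide_id`, `trait`, `rho`, `p`, `n` (rho/p are `NA`
#'   when fewer than 3 pairs remain).
#' @export
pearson_panel <- function(log2_mat, meta,
                          traits = c("abeta42", "ttau", "ptau",
                                     "ttau_abeta42", "moca"),
                          saturation_value = 1700,
                          peptides = NULL) {
  if (!all(traits %in% names(meta))) abort("Missing trait columns in `meta`.")
  amyloid_traits <- intersect(traits, c("abeta42", "ttau_abeta42"))
  long <- ratio_long(log2_mat)
  if (!is.null(peptides)) long <- long[long$peptide_id %in% peptides, ]
  purrr::map_dfr(traits, function(tr) {
    m <- meta[, unique(c("sample_id", tr, "abeta42"))]
    if (tr %in% amyloid_traits) {
      m <- m[is.na(m$abeta42) | m$abeta42 != saturation_value, ]
    }
    df <- inner_join(long, m, by = "sample_id")
    df <- df[!is.na(df[[tr]]), ]
    df |>
      group_by(.data$peptide_id) |>
      summarise(trait = tr, rho = {
        if (dplyr::n() < 3 || stats::sd(.data$value) == 0) NA_real_
        else stats::cor(.data$value, .data[[tr]])
      }, p = {
        if (dplyr::n() < 3 || stats::sd(.data$value) == 0 ||
            stats::sd(.data[[tr]]) == 0) NA_real_
        else stats::cor.test(.data$value, .data[[tr]])$p.value
      }, n = dplyr::n(), .groups = "drop")
  })
}

#' Correlate two per-peptide effect-size vectors
#'
#' Pearson correlation of log2 fold changes over the intersection of
#' peptide ids, as used to check concordance between a targeted assay and
#' an orthogonal discovery dataset.
#'
#' @param fc_a,fc_b Tibbles with `peptide_id` and `log2fc`.
#' @return List: `rho`, `p`, `n`, and `data` (the merged scatter table).
#' @export
correlate_effect_sizes <- function(fc_a, fc_b) {
  merged <- inner_join(fc_a[, c("peptide_id", "log2fc")],
                       fc_b[, c("peptide_id", "log2fc")],
                       by = "peptide_id", suffix = c("_a", "_b"))
  if (nrow(merged) == 0) abort("No shared peptides between the two effect-size tables.")
  if (nrow(merged) < 3) abort("Need at least 3 shared peptides.")
  ct <- stats::cor.test(merged$log2fc_a, merged$log2fc_b)
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(merged),
       data = merged)
}
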