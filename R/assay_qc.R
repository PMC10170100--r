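# Instrument-performance and sample-integrity analytics: isotopologue
# ladder detection limits, hemoglobin-based blood-contamination flags, and
# proteogenomic APOE genotype calls from allele-specific peptide presence.

#' Label-free CV per peptide and dilution level
#'
#' Computes the CV of raw peak areas for every peptide x amount cell of an
#' isotopologue dilution ladder and marks levels whose mean raw area is at
#' or below the noise floor as not detected.
#'
#' @param series A `dilution_series` (see [generate_dilution_series()]).
#' @return Tibble: `peptide_id`, `amount_fmol`, `n`, `mean_area`,
#'   `cv_percent`, `detected`.
#' @export
labelfree_cv_by_level <- function(series) {
  areas <- series$areas
  if (min(dplyr::count(areas, .data$peptide_id, .data$amount_fmol)$n) < 2) {
    abort("Need at least 2 injections per level.")
  }
  areas |>
    group_by(.data$peptide_id, .data$amount_fmol) |>
    summarise(n = dplyr::n(),
              mean_area = mean(.data$area),
              cv_percent = cv_percent(.data$area),
              .groups = "drop") |>
    mutate(detected = .data$mean_area > series$noise_floor)
}

#' Limit of detection and dynamic range from a dilution ladder
#'
#' For each peptide: the LOD is the lowest ladder amount that is detected
#' (mean area above the noise floor) with label-free CV at or below
#' `cv_threshold`; the dynamic range is the orders of magnitude
#' (log10 max/min) spanned by detected levels; linearity is the slope and
#' R-squared of log10(mean area) on log10(amount) over detected levels.
#'
#' @param series A `dilution_series`.
#' @param cv_threshold CV acceptance threshold in percent.
#' @return Tibble: `peptide_id`, `lod_fmol`, `n_detected`,
#'   `dynamic_range_orders`, `linearity_slope`, `linearity_r2`.
#' @export
estimate_lod <- function(series, cv_threshold = 20) {
  cvs <- labelfree_cv_by_level(series)
  cvs |>
    group_by(.data$peptide_id) |>
    group_modify(function(df, key) {
      det <- df[df$detected, ]
      if (nrow(det) == 0) {
        abort(sprintf("No level detected for peptide %s.", key$peptide_id))
      }
      ok <- det[det$cv_percent <= cv_threshold, ]
      fit <- if (nrow(det) >= 2) {
        stats::lm(log10(mean_area) ~ log10(amount_fmol), data = det)
      } else NULL
      tibble(
        lod_fmol = if (nrow(ok)) min(ok$amount_fmol) else NA_real_,
        n_detected = nrow(det),
        dynamic_range_orders = log10(max(det$amount_fmol) / min(det$amount_fmol)),
        linearity_slope = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[2]),
        linearity_r2 = if (is.null(fit)) NA_real_ else summary(fit)$r.squared
      )
    }) |>
    ungroup()
}

#' Flag potential blood contamination from hemoglobin peptides
#'
#' Scores each sample by the maximum, over the hemoglobin peptides, of the
#' robust z-score (median/MAD across samples) of its log2 ratio, and flags
#' samples whose score exceeds `threshold`. Flags are annotations only:
#' downstream statistics never auto-exclude flagged samples, mirroring the
#' practice of reporting contamination without correcting for it.
#'
#' @param ratios Ratio matrix tibble.
#' @param hb_peptides Ids of the hemoglobin peptide rows.
#' @param threshold Robust z flagging threshold.
#' @return Tibble: `sample_id`, `score`, `flagged`.
#' @export
flag_blood_contamination <- function(ratios, hb_peptides = c("HBA", "HBB"),
                                     threshold = 3) {
  assert_ratio_matrix(ratios)
  if (!all(hb_peptides %in% ratios$peptide_id)) {
    abort("Hemoglobin peptide rows missing from the ratio matrix.")
  }
  samples <- setdiff(names(ratios), "peptide_id")
  z <- sapply(hb_peptides, function(p) {
    x <- as.numeric(ratios[ratios$peptide_id == p, samples])
    if (any(x <= 0)) {
      nz <- x[x > 0]
      if (length(nz) == 0) abort(sprintf("Peptide %s is all-zero.", p))
      x[x <= 0] <- min(nz) / 2
    }
    robust_z(log2(x))
  })
  score <- apply(as.matrix(z), 1, max)
  tibble(sample_id = samples, score = score,
         flagged = is.finite(threshold) & score > threshold)
}

# presence pattern -> genotype truth table, rows in apoe_peptides() order
.apoe_pattern_table <- function() {
  pats <- vapply(apoe_genotypes(),
                 function(g) paste(as.integer(assign_apoe(g) > 0), collapse = ""),
                 character(1))
  setNames(names(pats), pats)
}

#' Call APOE genotype from allele-specific peptide presence
#'
#' Converts the four allele-specific peptide ratios of each sample into
#' presence bits (ratio above a fraction of that peptide's cohort median
#' among nonzero measurements) and maps the bit pattern through the
#' six-genotype truth table; any unmatched pattern is `indeterminate`.
#' A dosage score (ratio relative to the nonzero cohort median, so roughly
#' 0.5 for heterozygous and 1 for homozygous carriage) is reported as
#' corroboration but never overrides the presence pattern.
#'
#' @param ratios Ratio matrix tibble containing the four APOE peptide rows.
#' @param peptides The four allele-specific peptide ids, in
#'   [apoe_peptides()] order.
#' @param presence_frac Presence threshold as a fraction of the peptide's
#'   cohort median among nonzero values.
#' @return Tibble: `sample_id`, four presence-bit columns, `genotype`
#'   (`"indeterminate"` when unmatched), `dosage_score`.
#' @export
call_apoe <- function(ratios, peptides = apoe_peptides(),
                      presence_frac = 0.05) {
  assert_ratio_matrix(ratios)
  if (!all(peptides %in% ratios$peptide_id)) {
    abort("All four APOE allele-specific peptide rows are required.")
  }
  samples <- setdiff(names(ratios), "peptide_id")
  vals <- sapply(peptides, function(p) as.numeric(ratios[ratios$peptide_id == p, samples]))
  vals <- matrix(vals, ncol = length(peptides),
                 dimnames = list(samples, peptides))
  med <- apply(vals, 2, function(x) if (any(x > 0)) stats::median(x[x > 0]) else Inf)
  present <- sweep(vals, 2, presence_frac * med, ">")
  lookup <- .apoe_pattern_table()
  pattern <- apply(present, 1, function(b) paste(as.integer(b), collapse = ""))
  genotype <- unname(lookup[pattern])
  genotype[is.na(genotype)] <- "indeterminate"
  dosage <- rowMeans(sweep(vals, 2, med, "/") * present, na.rm = TRUE)
  out <- tibble(sample_id = samples)
  for (j in seq_along(peptides)) out[[peptides[j]]] <- unname(present[, j])
  out$genotype <- genotype
  out$dosage_score <- unname(dosage)
  out
}
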