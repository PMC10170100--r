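# Transition-level quantification: the rules a targeted SRM study applies
# between raw chromatogram areas and the analysis-ready log2 ratio matrix.

#' Integrate a chromatogram trace over a retention-time window
#'
#' Trapezoidal integral of intensity above a constant baseline, where the
#' baseline is the minimum intensity inside the window. A fixed automatic
#' baseline rule stands in for interactive peak-boundary adjustment;
#' interference is instead caught downstream by the ratio dot-product gate.
#'
#' @param trace Data frame with `time` (strictly increasing, minutes) and
#'   `intensity` columns, or a list with those elements.
#' @param rt_window Length-2 numeric window (minutes); defaults to the full
#'   trace span.
#' @return Non-negative area in intensity-minutes.
#' @export
integrate_trace <- function(trace, rt_window = NULL) {
  tt <- trace$time
  yy <- trace$intensity
  if (is.null(tt) || is.null(yy) || length(tt) != length(yy)) {
    abort("`trace` needs matching `time` and `intensity` vectors.")
  }
  if (is.null(rt_window)) rt_window <- range(tt)
  if (rt_window[1] >= rt_window[2]) abort("rt_window start must precede its end.")
  keep <- tt >= rt_window[1] & tt <= rt_window[2]
  if (sum(keep) < 2) abort("Fewer than 2 trace points in the integration window.")
  tt <- tt[keep]
  yy <- yy[keep] - min(yy[keep])
  max(0, sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2))
}

#' Total area ratio of light to heavy transitions
#'
#' Sums the three light and the three heavy transition areas and divides
#' light by heavy. A zero light sum is a legitimate measurement (an APOE
#' allele-specific peptide absent from the sample); a zero heavy sum is an
#' assay failure, since the heavy standard is always spiked.
#'
#' @param light_areas,heavy_areas Numeric 3-vectors of non-negative areas.
#' @return The dimensionless light/heavy ratio.
#' @export
total_area_ratio <- function(light_areas, heavy_areas) {
  if (length(light_areas) != 3 || length(heavy_areas) != 3) {
    abort("Expected exactly 3 light and 3 heavy transition areas.")
  }
  if (any(light_areas < 0) || any(heavy_areas < 0)) abort("Areas must be non-negative.")
  h <- sum(heavy_areas)
  if (h == 0) abort("Heavy transition areas sum to zero; the heavy standard was not detected.")
  sum(light_areas) / h
}

#' Ratio dot product of light and heavy transition profiles
#'
#' Cosine similarity of the two 3-dimensional transition-area vectors:
#' 1 means the light and heavy peak areas are in exactly the same ratio to
#' each other (co-elution of the endogenous peptide with its isotope
#' standard); values well below 1 indicate interference in one label.
#' Scale-invariant in each argument.
#'
#' @param light_areas,heavy_areas Numeric 3-vectors of non-negative areas.
#' @return Value in \[0, 1\], or `NA` when either vector has zero norm
#'   (undefined, distinct from a true 0).
#' @export
ratio_dot_product <- function(light_areas, heavy_areas) {
  if (length(light_areas) != 3 || length(heavy_areas) != 3) {
    abort("Expected exactly 3 light and 3 heavy transition areas.")
  }
  nl <- sqrt(sum(light_areas^2))
  nh <- sqrt(sum(heavy_areas^2))
  if (nl == 0 || nh == 0) return(NA_real_)
  sum(light_areas * heavy_areas) / (nl * nh)
}

#' Per-peptide, per-pool QC statistics
#'
#' Summarises replicate QC-pool measurements: CV (percent, sample SD over
#' mean of the raw ratios), mean and median ratio, and mean ratio dot
#' product.
#'
#' @param quants Tibble with `peptide_id`, `pool`, `total_area_ratio` and
#'   `rdotp` columns (see [generate_qc_pools()]).
#' @return Tibble: `peptide_id`, `pool`, `n`, `cv_percent`, `mean_ratio`,
#'   `median_ratio`, `rdotp_mean`.
#' @export
summarize_qc <- function(quants) {
  need <- c("peptide_id", "pool", "total_area_ratio", "rdotp")
  if (!all(need %in% names(quants))) {
    abort(sprintf("`quants` must have columns %s.", paste(need, collapse = ", ")))
  }
  counts <- dplyr::count(quants, .data$peptide_id, .data$pool)
  if (any(counts$n < 2)) {
    abort("Each peptide needs at least 2 replicates per pool to compute a CV.")
  }
  quants |>
    group_by(.data$peptide_id, .data$pool) |>
    summarise(
      n = dplyr::n(),
      cv_percent = cv_percent(.data$total_area_ratio),
      mean_ratio = mean(.data$total_area_ratio),
      median_ratio = stats::median(.data$total_area_ratio),
      rdotp_mean = mean(.data$rdotp),
      .groups = "drop"
    )
}

#' Apply QC acceptance gates to peptide statistics
#'
#' A peptide is retained when its ratio CV is at or below `cv_max` in at
#' least one QC pool AND its mean ratio dot product is at least `rdotp_min`
#' in both pools. The report records which gate failed: `"cv"`, `"rdotp"`,
#' or `"cv+rdotp"`.
#'
#' @param qc_stats Output of [summarize_qc()] containing both pools for
#'   every peptide.
#' @param cv_max CV gate in percent (boundary inclusive).
#' @param rdotp_min Minimum acceptable mean ratio dot product.
#' @return Tibble: `peptide_id`, pool-wise CVs and rdotp means, `accepted`,
#'   `reason`.
#' @export
apply_gates <- function(qc_stats, cv_max = 20, rdotp_min = 0.90) {
  wide <- qc_stats |>
    select("peptide_id", "pool", "cv_percent", "rdotp_mean") |>
    tidyr::pivot_wider(names_from = "pool",
                       values_from = c("cv_percent", "rdotp_mean"))
  need <- c("cv_percent_ATneg", "cv_percent_ATpos",
            "rdotp_mean_ATneg", "rdotp_mean_ATpos")
  if (!all(need %in% names(wide))) {
    abort("apply_gates() needs statistics for both pools (ATneg and ATpos) per peptide.")
  }
  wide |>
    mutate(
      cv_pass = pmin(.data$cv_percent_ATneg, .data$cv_percent_ATpos) <= cv_max,
      rdotp_pass = .data$rdotp_mean_ATneg >= rdotp_min &
        .data$rdotp_mean_ATpos >= rdotp_min,
      accepted = .data$cv_pass & .data$rdotp_pass,
      reason = dplyr::case_when(
        accepted ~ NA_character_,
        !cv_pass & !rdotp_pass ~ "cv+rdotp",
        !cv_pass ~ "cv",
        TRUE ~ "rdotp"
      )
    ) |>
    select(-"cv_pass", -"rdotp_pass")
}

#' Impute zero ratios as half the row minimum
#'
#' Replaces every zero in a peptide row by half the smallest nonzero ratio
#' of that row, so that log2 transformation is defined. Zeros occur only
#' for APOE allele-specific peptides genuinely absent from a genotype.
#'
#' @param ratios Ratio matrix tibble (`peptide_id` + sample columns).
#' @return The imputed matrix; nonzero cells are untouched.
#' @export
impute_zeros <- function(ratios) {
  assert_ratio_matrix(ratios)
  samples <- setdiff(names(ratios), "peptide_id")
  vals <- as.matrix(ratios[samples])
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    if (any(row == 0)) {
      nz <- row[row > 0]
      if (length(nz) == 0) {
        abort(sprintf("Peptide %s has no nonzero measurement; cannot impute.",
                      ratios$peptide_id[i]))
      }
      vals[i, row == 0] <- min(nz) / 2
    }
  }
  bind_cols(tibble(peptide_id = ratios$peptide_id),
            as_tibble(vals, .name_repair = "minimal"))
}

#' Log2-transform a ratio matrix
#'
#' Elementwise log2 of the (already imputed) ratio matrix. Since log2 of
#' zero is undefined, zeros must first be replaced via [impute_zeros()].
#'
#' @param ratios Ratio matrix tibble with strictly positive entries.
#' @return Tibble of the same shape with log2 values.
#' @export
log2_matrix <- function(ratios) {
  assert_ratio_matrix(ratios)
  samples <- setdiff(names(ratios), "peptide_id")
  vals <- as.matrix(ratios[samples])
  if (any(vals <= 0)) {
    abort("Matrix contains non-positive ratios; run impute_zeros() first (log2 of zero is undefined).")
  }
  bind_cols(tibble(peptide_id = ratios$peptide_id),
            as_tibble(log2(vals), .name_repair = "minimal"))
}

#' Integrate rendered traces back to transition areas
#'
#' Convenience inverse of [render_traces()]: integrates each transition
#' trace with [integrate_trace()] and returns areas in the wide layout used
#' by the quantification functions, with recomputed total area ratio and
#' ratio dot product.
#'
#' @param traces Long trace tibble from [render_traces()].
#' @param rt_window Optional integration window passed through.
#' @return Tibble: `sample_id`, `peptide_id`, `light_1..3`, `heavy_1..3`,
#'   `total_area_ratio`, `rdotp`.
#' @export
integrate_traces <- function(traces, rt_window = NULL) {
  areas <- traces |>
    group_by(.data$sample_id, .data$peptide_id, .data$label, .data$transition) |>
    summarise(area = integrate_trace(list(time = .data$time, intensity = .data$intensity),
                                     rt_window),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("label", "transition"),
                       values_from = "area", names_sep = "_")
  areas |>
    rowwise() |>
    mutate(
      total_area_ratio = total_area_ratio(
        c(.data$light_1, .data$light_2, .data$light_3),
        c(.data$heavy_1, .data$heavy_2, .data$heavy_3)),
      rdotp = ratio_dot_product(
        c(.data$light_1, .data$light_2, .data$light_3),
        c(.data$heavy_1, .data$heavy_2, .data$heavy_3))
    ) |>
    ungroup()
}
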