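# ggplot2 displays for the main result types.

#' Volcano plot of differential abundance results
#'
#' @param diff Tibble with `log2fc` and a p-value column.
#' @param p_col Name of the p-value column to plot (e.g. `"tukey_p"`,
#'   `"t_p"` or `"bh_fdr"`).
#' @param alpha Significance threshold drawn as a dashed line.
#' @param label_top Number of most significant peptides to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, p_col = "tukey_p", alpha = 0.05, label_top = 10) {
  stopifnot(all(c("peptide_id", "log2fc", p_col) %in% names(diff)))
  df <- diff |>
    mutate(
      p = .data[[p_col]],
      status = dplyr::case_when(
        .data$p < alpha & .data$log2fc > 0 ~ "up",
        .data$p < alpha & .data$log2fc < 0 ~ "down",
        TRUE ~ "ns"
      )
    )
  lab <- df |> filter(.data$p < alpha) |> arrange(.data$p) |> utils::head(label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$peptide_id),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = expression(-log[10](p)),
                  colour = NULL)
}

#' ROC curve of a single-peptide classifier
#'
#' @param object An `srm_roc` object from [roc_single()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srm_roc
#' @export
autoplot.srm_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.1f%% (DeLong CI %.1f-%.1f%%)",
                      100 * object$auc, 100 * object$ci_low, 100 * object$ci_high))
}

#' Dilution-ladder linearity plot
#'
#' Mean raw area against spiked amount on log10 axes, one line per
#' peptide, with the detection floor marked.
#'
#' @param series A `dilution_series`.
#' @return A ggplot object.
#' @export
plot_dilution_linearity <- function(series) {
  cvs <- labelfree_cv_by_level(series)
  ggplot2::ggplot(cvs, ggplot2::aes(.data$amount_fmol, .data$mean_area,
                                    colour = .data$peptide_id)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$detected)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = series$noise_floor, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "amount (fmol)", y = "mean raw area",
                  shape = "detected", colour = NULL)
}

#' Stage heatmap of per-comparison log2 fold changes
#'
#' @param diff Output of [anova_tukey()].
#' @param stages Optional `stage_result` used to order rows by category.
#' @return A ggplot object.
#' @export
plot_stage_heatmap <- function(diff, stages = NULL) {
  df <- diff
  if (!is.null(stages)) {
    ord <- stages$calls |> arrange(.data$category, .data$peptide_id)
    df <- df[df$peptide_id %in% ord$peptide_id, ]
    df$peptide_id <- factor(df$peptide_id, levels = rev(ord$peptide_id))
  }
  df$stars <- cut(df$tukey_p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("***", "**", "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(.data$comparison, .data$peptide_id,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC")
}
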