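# ROC diagnostics: rank-statistic AUC (identical to the AUC of a
# single-predictor logistic fit, whose score is monotone in the predictor),
# DeLong variance and confidence interval, Youden-optimal operating point,
# and stratified k-fold cross-validated AUC on pooled out-of-fold
# predictions.

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (is.null(positive)) {
    if (length(lev) != 2) abort("Give `positive` when labels have more than two levels.")
    positive <- lev[2]
  }
  labels == positive
}

# midrank (Mann-Whitney) AUC of scores for cases vs controls; ties count 1/2
auc_rank <- function(scores, is_case) {
  m <- sum(is_case)
  n <- sum(!is_case)
  if (m == 0 || n == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_case]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement variance of the AUC
delong_se <- function(scores, is_case) {
  x <- scores[is_case]
  y <- scores[!is_case]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' Single-peptide ROC analysis with DeLong interval
#'
#' Computes the AUC as the Mann-Whitney rank statistic (ties counted one
#' half), auto-orienting the predictor so the reported AUC is at least 0.5
#' with the direction noted. The DeLong placement variance gives the 95%
#' confidence interval and a two-sided p-value against AUC = 0.5;
#' sensitivity, specificity and accuracy are reported at the
#' Youden-optimal cutoff (ties at equal J broken toward higher
#' specificity).
#'
#' @param values Numeric predictor (e.g. a peptide's log2 ratios).
#' @param labels Binary class labels (logical, 0/1, or two-level with
#'   `positive` naming the case class).
#' @param positive Case label when `labels` is not already logical/0-1.
#' @param conf_level Confidence level of the DeLong interval.
#' @return Object of class `srm_roc`.
#' @export
roc_single <- function(values, labels, positive = NULL, conf_level = 0.95) {
  y <- as_binary_labels(labels, positive)
  keep <- !is.na(values) & !is.na(y)
  values <- values[keep]
  y <- y[keep]
  if (!any(y) || all(y)) abort("Both classes must be present.")

  direction <- if (auc_rank(values, y) >= 0.5) 1 else -1
  w <- values * direction
  auc <- auc_rank(w, y)
  se <- delong_se(w, y)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else 2 * stats::pnorm(-abs(auc - 0.5) / se)

  # Youden-optimal operating point over midpoint cutoffs
  cuts <- sort(unique(w))
  cuts <- c(-Inf, (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2, Inf)
  sens <- vapply(cuts, function(ct) mean(w[y] > ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(w[!y] <= ct), numeric(1))
  j <- sens + spec - 1
  ord <- order(-j, -spec, -cuts)
  best <- ord[1]

  m <- sum(y)
  n <- sum(!y)
  curve <- tibble(cutoff = cuts, fpr = 1 - spec, tpr = sens)
  out <- list(
    auc = auc, ci_low = ci[1], ci_high = ci[2], se = se, p = p,
    sensitivity = sens[best], specificity = spec[best],
    accuracy = (sens[best] * m + spec[best] * n) / (m + n),
    cutoff = direction * cuts[best], direction = direction,
    n_case = m, n_control = n, conf_level = conf_level, curve = curve
  )
  class(out) <- "srm_roc"
  out
}

#' @export
print.srm_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%.0f%% DeLong CI %.3f-%.3f), p = %.3g\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  operating point: sens %.3f, spec %.3f, acc %.3f at cutoff %.4g%s\n",
              x$sensitivity, x$specificity, x$accuracy, x$cutoff,
              if (x$direction < 0) " (inverted predictor)" else ""))
  invisible(x)
}

#' @rdname tidy.srm_roc
#' @method glance srm_roc
#' @export
glance.srm_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         p = x$p, n_case = x$n_case, n_control = x$n_control)
}

#' Tidy an `srm_roc` object
#'
#' `tidy()` returns the full one-row summary including the Youden operating
#' point; `glance()` returns the AUC, its DeLong interval, p-value and
#' class sizes.
#'
#' @param x An `srm_roc` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy srm_roc
#' @export
tidy.srm_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
         p = x$p, sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy, cutoff = x$cutoff, direction = x$direction,
         n_case = x$n_case, n_control = x$n_control)
}

#' Stratified k-fold cross-validated AUC
#'
#' Builds outcome-balanced folds (per-class round-robin assignment after a
#' seeded shuffle), fits a single-predictor binomial GLM on each training
#' split, pools the out-of-fold linear predictors, and reports the rank
#' AUC of the pooled predictions with its DeLong confidence interval.
#'
#' @param values Numeric predictor.
#' @param labels Binary class labels.
#' @param k Number of folds; every class must have at least `k` members.
#' @param seed RNG seed controlling fold assignment (same seed, same
#'   folds and value).
#' @param positive Case label when needed.
#' @return List: `cv_auc`, `ci_low`, `ci_high`, `se`, `k`, `folds` (fold
#'   index per sample), `scores` (pooled out-of-fold predictions).
#' @export
cv_auc <- function(values, labels, k = 10, seed = 1L, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (min(sum(y), sum(!y)) < k) {
    abort(sprintf("Each class needs at least k = %d members; use a smaller k.", k))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial(),
                 data = data.frame(y = y[!test], x = values[!test]))
    )
    scores[test] <- stats::predict(fit, newdata = data.frame(x = values[test]),
                                   type = "link")
  }
  auc <- auc_rank(scores, y)
  se <- delong_se(scores, y)
  zq <- stats::qnorm(0.975)
  list(cv_auc = auc,
       ci_low = max(0, auc - zq * se), ci_high = min(1, auc + zq * se),
       se = se, k = k, folds = folds, scores = scores)
}

#' Per-peptide ROC table for a two-group comparison
#'
#' Runs [roc_single()] on every peptide row of the log2 matrix for the
#' given case/control conditions and returns one tidy row per peptide.
#'
#' @param log2_mat Log2 ratio matrix tibble.
#' @param meta Sample metadata with `sample_id` and `condition`.
#' @param case,control Condition labels (case is the positive class).
#' @param peptides Optional subset of peptide ids.
#' @return Tibble of tidy ROC rows with `peptide_id` and `comparison`.
#' @export
roc_panel <- function(log2_mat, meta, case, control, peptides = NULL) {
  long <- join_long(log2_mat, meta, peptides)
  long <- long[long$condition %in% c(case, control), ]
  purrr::map_dfr(split(long, long$peptide_id), function(df) {
    r <- roc_single(df$value, df$condition == case)
    bind_cols(tibble(peptide_id = df$peptide_id[1],
                     comparison = comparison_label(case, control)),
              tidy(r))
  })
}

#' Rank ROC results and keep the top performers
#'
#' Orders a ROC table by descending AUC, breaking ties by narrower DeLong
#' interval and then by peptide id, and returns the first `top_k` rows.
#'
#' @param roc_tbl Output of [roc_panel()] (optionally several comparisons).
#' @param comparison Optional comparison label to filter on.
#' @param top_k Number of rows to keep; all rows if fewer are available.
#' @return The ordered, truncated tibble.
#' @export
rank_top <- function(roc_tbl, comparison = NULL, top_k = 5) {
  if (!is.null(comparison)) roc_tbl <- roc_tbl[roc_tbl$comparison == comparison, ]
  if (nrow(roc_tbl) == 0) abort("No ROC results to rank.")
  roc_tbl |>
    mutate(.ci_width = .data$ci_high - .data$ci_low) |>
    arrange(desc(.data$auc), .data$.ci_width, .data$peptide_id) |>
    select(-".ci_width") |>
    utils::head(top_k)
}
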