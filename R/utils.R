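#' @importFrom rlang .data abort warn `%||%`
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd median mad rnorm runif rbinom setNames
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# sd of log(x) giving a multiplicative coefficient of variation of cv_percent
sdlog_from_cv <- function(cv_percent) sqrt(log1p((cv_percent / 100)^2))

# n multiplicative lognormal noise factors with mean exactly 1
rlnorm_cv <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  s <- sdlog_from_cv(cv_percent)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Coefficient of variation as a percentage
#'
#' Sample (n - 1) standard deviation divided by the mean, times 100. Computed
#' on raw (not log) values, the convention used for assay precision reporting.
#'
#' @param x Numeric vector with at least two values.
#' @return CV in percent; `NA` when the mean is zero (undefined).
#' @export
cv_percent <- function(x) {
  if (length(x) < 2) abort("cv_percent() needs at least 2 replicate values.")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

# robust z-scores: deviation from median in MAD units; a constant vector
# scores 0 everywhere rather than 0/0
robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  dev <- x - med
  if (s == 0) return(ifelse(dev == 0, 0, Inf * sign(dev)))
  dev / s
}

assert_ratio_matrix <- function(ratios, arg = "ratios") {
  if (!is.data.frame(ratios) || !"peptide_id" %in% names(ratios)) {
    abort(sprintf("`%s` must be a data frame with a `peptide_id` first column.", arg))
  }
  samp <- names(ratios)[names(ratios) != "peptide_id"]
  if (length(samp) == 0) abort(sprintf("`%s` has no sample columns.", arg))
  if (anyDuplicated(samp)) abort("Duplicate sample ids in ratio matrix columns.")
  if (anyDuplicated(ratios$peptide_id)) abort("Duplicate peptide ids in ratio matrix.")
  vals <- as.matrix(ratios[samp])
  if (!is.numeric(vals)) abort(sprintf("Sample columns of `%s` must be numeric.", arg))
  if (anyNA(vals)) abort(sprintf("`%s` contains missing cells; the matrix layout permits zeros but no blanks.", arg))
  if (any(vals < 0)) abort(sprintf("`%s` contains negative ratios.", arg))
  invisible(ratios)
}

# long view of a peptides-by-samples ratio matrix
ratio_long <- function(ratios) {
  tidyr::pivot_longer(ratios, -"peptide_id",
                      names_to = "sample_id", values_to = "value")
}
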