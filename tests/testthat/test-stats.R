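make_l2 <- function(values_by_group) {
  # values_by_group: named list of per-group value vectors for one peptide
  n <- sum(lengths(values_by_group))
  meta <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    condition = rep(names(values_by_group), lengths(values_by_group))
  )
  l2 <- tibble::tibble(peptide_id = "PEP")
  l2[meta$sample_id] <- as.list(unlist(values_by_group, use.names = FALSE))
  list(l2 = l2, meta = meta)
}

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, mean = 0.4)
    fx <- make_l2(list(Control = x, AD = y))
    res <- anova_tukey(fx$l2, fx$meta, groups = c("Control", "AD"))
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(res$f_stat[1], unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(res$p_anova[1], tt$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc[1], mean(y) - mean(x), tolerance = 1e-10)
    expect_equal(res$comparison[1], "AD_vs_CT")
  }
})

test_that("a constant peptide yields F = 0 and p = 1 everywhere", {
  fx <- make_l2(list(Control = rep(2, 5), AsymAD = rep(2, 5), AD = rep(2, 5)))
  res <- anova_tukey(fx$l2, fx$meta)
  expect_true(all(res$f_stat == 0))
  expect_true(all(res$p_anova == 1))
  expect_true(all(res$tukey_p == 1))
})

test_that("Tukey-adjusted p is never below the unadjusted pairwise p", {
  set.seed(52)
  for (i in 1:10) {
    g <- rep(c("Control", "AsymAD", "AD"), each = 10)
    v <- rnorm(30) + rep(c(0, 0.3, 0.6) * (i %% 3), each = 10)
    fx <- make_l2(split(v, g))
    res <- anova_tukey(fx$l2, fx$meta)
    raw <- pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)$p.value
    raw_p <- c(raw["AsymAD", "AD"], raw["Control", "AD"], raw["Control", "AsymAD"])
    for (cmp_raw in raw_p) {
      expect_true(any(res$tukey_p >= cmp_raw - 1e-12))
    }
    expect_true(all(res$tukey_p >= min(raw_p) - 1e-12))
  }
})

test_that("a strong synthetic effect is detected in all three comparisons", {
  panel <- default_peptide_panel(effect_size = 1)
  panel <- panel[panel$peptide_id %in% c("GAPDH", "PON1", "HBA", "HBB"), ]
  d <- cohort_design(panel = panel, contamination_fraction = 0)
  co <- generate_cohort(d, seed = 53)
  l2 <- log2_matrix(impute_zeros(co$ratios))
  res <- anova_tukey(l2, co$meta, peptides = "GAPDH")  # progressive: 0.5 then 1.0
  expect_true(all(res$tukey_p < 0.001))
})

test_that("Welch t-tests with BH correction match an independent BH ladder", {
  set.seed(54)
  n <- 10
  l2 <- tibble::tibble(peptide_id = sprintf("P%02d", 1:n))
  meta <- tibble::tibble(sample_id = sprintf("S%03d", 1:40),
                         condition = rep(c("Control", "AD"), each = 20))
  vals <- matrix(rnorm(n * 40), nrow = n)
  vals[1:3, 21:40] <- vals[1:3, 21:40] + 1
  l2[meta$sample_id] <- as.data.frame(vals)
  res <- ttest_bh(l2, meta, "AD", "Control")
  expect_equal(res$bh_fdr, bh_ladder(res$t_p), tolerance = 1e-12)
  # BH is monotone along sorted p
  o <- order(res$t_p)
  expect_true(all(diff(res$bh_fdr[o]) >= -1e-12))
  expect_true(all(res$bh_fdr >= res$t_p - 1e-12))
  # single peptide: FDR equals p
  single <- ttest_bh(l2[1, ], meta, "AD", "Control")
  expect_equal(single$bh_fdr, single$t_p)
})

test_that("degenerate constant groups follow the documented p conventions", {
  fx <- make_l2(list(Control = rep(1, 4), AD = rep(1, 4)))
  expect_equal(ttest_bh(fx$l2, fx$meta, "AD", "Control")$t_p, 1)
  fx2 <- make_l2(list(Control = rep(1, 4), AD = rep(2, 4)))
  r2 <- ttest_bh(fx2$l2, fx2$meta, "AD", "Control")
  expect_equal(r2$t_p, 0)
  expect_equal(r2$log2fc, 1)
})

test_that("null t-test p-values are uniform at the 5% level", {
  set.seed(55)
  hits <- 0; total <- 0
  for (rep in 1:40) {
    n <- 30
    l2 <- tibble::tibble(peptide_id = sprintf("P%02d", 1:n))
    meta <- tibble::tibble(sample_id = sprintf("S%03d", 1:60),
                           condition = rep(c("Control", "AD"), each = 30))
    l2[meta$sample_id] <- as.data.frame(matrix(rnorm(n * 60), nrow = n))
    res <- ttest_bh(l2, meta, "AD", "Control")
    hits <- hits + sum(res$t_p < 0.05)
    total <- total + n
  }
  bounds <- qbinom(c(5e-4, 1 - 5e-4), total, 0.05) / total
  expect_gte(hits / total, bounds[1])
  expect_lte(hits / total, bounds[2])
})

test_that("stage classification follows the significance/direction rule table", {
  mk_diff <- function(pid, fc_a, p_a, fc_b, p_b, fc_c = fc_a + fc_b, p_c = 0.5) {
    tibble::tibble(
      peptide_id = pid,
      comparison = c("AsymAD_vs_CT", "AD_vs_AsymAD", "AD_vs_CT"),
      log2fc = c(fc_a, fc_b, fc_c),
      tukey_p = c(p_a, p_b, p_c)
    )
  }
  diff <- dplyr::bind_rows(
    mk_diff("early_up", 0.7, 0.001, 0.05, 0.8),
    mk_diff("progressive_up", 0.4, 0.001, 0.4, 0.001),
    mk_diff("progressive_dn", -0.4, 0.001, -0.4, 0.001),
    mk_diff("reversing", 0.7, 0.001, -0.7, 0.001),
    mk_diff("flat", 0.01, 0.9, 0.01, 0.9, 0.02, 0.9),
    mk_diff("late_only", 0.05, 0.9, 0.6, 0.001)
  )
  st <- classify_stage(diff)
  calls <- setNames(st$calls$category, st$calls$peptide_id)
  expect_equal(unname(calls["early_up"]), "early")
  expect_equal(unname(calls["progressive_up"]), "progressive")
  expect_equal(unname(calls["progressive_dn"]), "progressive")
  expect_equal(unname(calls["reversing"]), "reversing")
  expect_equal(unname(calls["flat"]), "unchanged")
  expect_equal(unname(calls["late_only"]), "other")
  expect_equal(st$sig_counts$n_significant[st$sig_counts$comparison == "AsymAD_vs_CT"], 4)
  expect_equal(sum(st$venn$count), 5)  # peptides significant anywhere

  # pure function of the triples: permutation of rows changes nothing
  st2 <- classify_stage(diff[sample(nrow(diff)), ])
  expect_equal(dplyr::arrange(st2$calls, peptide_id),
               dplyr::arrange(st$calls, peptide_id))
})

test_that("trait correlations respect the amyloid saturation exclusion", {
  set.seed(56)
  n <- 100
  meta <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:n),
    abeta42 = c(rep(1700, 5), runif(n - 5, 300, 1600)),
    ttau = runif(n, 100, 500),
    ptau = runif(n, 5, 60),
    moca = sample(10:30, n, replace = TRUE)
  )
  meta$ttau_abeta42 <- meta$ttau / meta$abeta42
  l2 <- tibble::tibble(peptide_id = "PEP")
  l2[meta$sample_id] <- as.list(rnorm(n))
  res <- pearson_panel(l2, meta)
  expect_equal(res$n[res$trait == "abeta42"], 95)
  expect_equal(res$n[res$trait == "ttau_abeta42"], 95)
  expect_equal(res$n[res$trait == "moca"], 100)
  expect_equal(res$n[res$trait == "ttau"], 100)

  # perfect and anti-perfect correlation against a peptide row
  vals <- as.numeric(l2[1, -1])
  meta2 <- meta
  meta2$ttau <- vals
  meta2$ptau <- -vals
  meta2$ttau_abeta42 <- meta2$ttau / meta2$abeta42
  res2 <- pearson_panel(l2, meta2, traits = c("ttau", "ptau"))
  expect_equal(res2$rho[res2$trait == "ttau"], 1, tolerance = 1e-12)
  expect_lt(res2$p[res2$trait == "ttau"], 1e-100)
  expect_equal(res2$rho[res2$trait == "ptau"], -1, tolerance = 1e-12)
})

test_that("effect-size concordance is scale invariant with a tight null", {
  set.seed(57)
  fc_a <- tibble::tibble(peptide_id = sprintf("P%02d", 1:40),
                         log2fc = rnorm(40))
  same <- correlate_effect_sizes(fc_a, fc_a)
  expect_equal(same$rho, 1, tolerance = 1e-12)
  halved <- fc_a
  halved$log2fc <- 0.5 * halved$log2fc
  expect_equal(correlate_effect_sizes(fc_a, halved)$rho, 1, tolerance = 1e-12)

  null_rhos <- replicate(200, {
    b <- fc_a
    b$log2fc <- rnorm(40)
    a <- fc_a
    a$log2fc <- rnorm(40)
    correlate_effect_sizes(a, b)$rho
  })
  expect_gte(mean(abs(null_rhos) < 0.4), 0.95)

  other <- tibble::tibble(peptide_id = "ZZZ", log2fc = 1)
  expect_error(correlate_effect_sizes(fc_a, other), "shared")
})
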