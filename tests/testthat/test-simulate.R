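test_that("cohort generator reproduces the study layout deterministically", {
  d <- cohort_design()
  co <- generate_cohort(d, seed = 21)
  expect_equal(dim(co$ratios), c(62, 391))  # 62 peptides, id column + 390 samples
  expect_equal(unname(table(co$meta$condition)[c("Control", "AsymAD", "AD")]),
               c(133, 127, 130), ignore_attr = TRUE)
  expect_false(anyDuplicated(co$meta$run_order) > 0)
  expect_true(all(co$meta$moca >= 0 & co$meta$moca <= 30))
  expect_true(all(co$meta$abeta42 <= 1700))
  co2 <- generate_cohort(d, seed = 21)
  expect_identical(co$ratios, co2$ratios)
  expect_identical(co$meta, co2$meta)
  co3 <- generate_cohort(d, seed = 22)
  expect_false(identical(co$ratios, co3$ratios))
})

test_that("zero-effect panels produce no systematic group separation", {
  d <- cohort_design(panel = default_peptide_panel(effect_size = 0),
                     contamination_fraction = 0)
  co <- generate_cohort(d, seed = 23)
  l2 <- log2_matrix(impute_zeros(co$ratios))
  long <- tidyr::pivot_longer(l2, -peptide_id, names_to = "sample_id") |>
    dplyr::inner_join(co$meta[, c("sample_id", "condition")], by = "sample_id") |>
    dplyr::filter(condition %in% c("Control", "AD"),
                  !peptide_id %in% apoe_peptides())
  checks <- long |>
    dplyr::group_by(peptide_id) |>
    dplyr::summarise(
      diff = mean(value[condition == "AD"]) - mean(value[condition == "Control"]),
      se = sqrt(var(value[condition == "AD"]) / sum(condition == "AD") +
                  var(value[condition == "Control"]) / sum(condition == "Control")))
  expect_gte(mean(abs(checks$diff) < 3 * checks$se), 0.95)
})

test_that("QC pools give the requested replicate structure and pool effects", {
  d <- cohort_design()
  qc <- generate_qc_pools(d, seed = 24)
  expect_equal(length(unique(qc$quants$sample_id)), 30)  # 15 AT- and 15 AT+
  expect_equal(nrow(qc$meta), 30)
  expect_equal(sum(qc$meta$condition == "QC_ATneg"), 15)
  # AT- pool carries the high-amyloid, low-tau immunoassay profile
  expect_equal(unique(qc$meta$abeta42[qc$meta$condition == "QC_ATneg"]), 1457.3)
  expect_equal(unique(qc$meta$ptau[qc$meta$condition == "QC_ATpos"]), 33.1)

  smoc1 <- qc$quants[qc$quants$peptide_id == "SMOC1", ]
  expect_gt(mean(smoc1$total_area_ratio[smoc1$pool == "ATpos"]),
            mean(smoc1$total_area_ratio[smoc1$pool == "ATneg"]))

  d2 <- cohort_design(qc_replicates = 2)
  qc2 <- generate_qc_pools(d2, seed = 24)
  expect_equal(length(unique(qc2$quants$sample_id)), 4)

  qc3 <- generate_qc_pools(d, seed = 24)
  expect_identical(qc$quants, qc3$quants)
})

test_that("rendered peaks hold their area, co-elute, and flatten at zero", {
  q <- make_quant(light = c(600, 300, 100), heavy = c(1200, 600, 200))
  tr <- render_traces(q, peak_sigma = 0.05, dt = 0.002, seed = 25)
  a <- tr |>
    dplyr::filter(label == "light", transition == 1) |>
    (\(x) integrate_trace(list(time = x$time, intensity = x$intensity)))()
  expect_equal(a, 600, tolerance = 0.01)
  apex <- tr |>
    dplyr::group_by(label) |>
    dplyr::summarise(apex = time[which.max(intensity)])
  expect_equal(apex$apex[1], apex$apex[2], tolerance = 0.01)

  q0 <- make_quant(light = c(0, 0, 0), heavy = c(100, 100, 100))
  tr0 <- render_traces(q0, seed = 25)
  expect_true(all(tr0$intensity[tr0$label == "light"] == 0))

  expect_error(render_traces(make_quant(c(1, 1, 1), c(1, 1, 1), rt = 15)),
               "gradient")
})

test_that("an interfering shoulder on one light transition depresses rdotp", {
  q <- make_quant(light = c(500, 400, 300), heavy = c(1000, 800, 600))
  clean <- integrate_traces(render_traces(q, interference_rate = 0, seed = 26))
  dirty <- integrate_traces(render_traces(q, interference_rate = 1, seed = 26))
  expect_lt(dirty$rdotp, clean$rdotp)
  expect_gt(clean$rdotp, 0.999)
})

test_that("dilution ladder spans 10-fold steps with an undetectable bottom rung", {
  s <- generate_dilution_series(seed = 27)
  expect_equal(nrow(s$areas), 6 * 5 * 20)
  expect_equal(sort(unique(s$areas$amount_fmol)), c(0.1, 1, 10, 100, 1000))
  expect_equal(diff(log10(sort(s$levels_fmol))), rep(1, 4))
  low <- s$areas |>
    dplyr::filter(amount_fmol == 0.1) |>
    dplyr::group_by(peptide_id) |>
    dplyr::summarise(m = mean(area))
  expect_true(all(low$m < s$noise_floor))
  # proportional response: log-log slope near 1 over clearly detected levels
  fits <- s$areas |>
    dplyr::filter(amount_fmol >= 1) |>
    dplyr::group_by(peptide_id, amount_fmol) |>
    dplyr::summarise(m = mean(area), .groups = "drop_last") |>
    dplyr::summarise(slope = coef(lm(log10(m) ~ log10(amount_fmol)))[2])
  expect_true(all(fits$slope > 0.9 & fits$slope < 1.1))
  s2 <- generate_dilution_series(seed = 27)
  expect_identical(s$areas, s2$areas)
})

test_that("APOE allele dosage follows the allele-to-peptide map", {
  s <- assign_apoe("E3/E3")
  expect_equal(unname(s), c(0, 0, 2, 2))
  expect_true(all(assign_apoe("E2/E4") >= 1))
  expect_equal(unname(assign_apoe("E2/E2")["LAVYQAGAR"]), 0)
  expect_equal(unname(assign_apoe("E4/E4")), c(0, 2, 0, 2))
  # dosage sums to 2 alleles x 2 peptides per allele
  for (g in c("E2/E2", "E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4")) {
    expect_equal(sum(assign_apoe(g)), 4)
  }
  expect_error(assign_apoe("E1/E3"), "genotype")
})

test_that("blood spikes hit only hemoglobin rows of the selected samples", {
  m <- small_matrix() |>
    dplyr::bind_rows(tibble::tibble(peptide_id = c("HBA", "HBB"),
                                    S1 = c(0.1, 0.2), S2 = c(0.1, 0.2)))
  none <- inject_blood_contamination(m, fraction = 0, seed = 28)
  expect_identical(none$ratios, m)
  expect_false(any(none$flags$contaminated))
  all_hit <- inject_blood_contamination(m, fraction = 1, fold = 10, seed = 28)
  expect_equal(as.numeric(all_hit$ratios[all_hit$ratios$peptide_id == "HBB", -1]),
               c(2, 2))
  expect_identical(all_hit$ratios[all_hit$ratios$peptide_id == "PEP_A", ],
                   m[m$peptide_id == "PEP_A", ])
  expect_error(inject_blood_contamination(m, fraction = 1.5), "fraction")
  expect_error(inject_blood_contamination(small_matrix()), "Hemoglobin")
})
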