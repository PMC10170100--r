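# Shared fixtures and independent oracles used across the test files.

# exhaustive pair-counting AUC: P(case > control) + 0.5 P(tie)
brute_force_auc <- function(values, is_case) {
  x <- values[is_case]
  y <- values[!is_case]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(x) * length(y))
}

# independent Benjamini-Hochberg ladder: sort, scale by m/i, enforce
# monotonicity from the largest p downward
bh_ladder <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# minimal valid ratio matrix
small_matrix <- function() {
  tibble::tibble(
    peptide_id = c("PEP_A", "PEP_B"),
    S1 = c(1.25, 0.5),
    S2 = c(2.5, 0.125)
  )
}

# one quant row with chosen transition areas, for trace rendering
make_quant <- function(light, heavy, rt = 7, sample_id = "QC1",
                       peptide_id = "PEP") {
  tibble::tibble(
    sample_id = sample_id, peptide_id = peptide_id,
    light_1 = light[1], light_2 = light[2], light_3 = light[3],
    heavy_1 = heavy[1], heavy_2 = heavy[2], heavy_3 = heavy[3],
    rt_apex = rt
  )
}

# six-row transition list (3 light + 3 heavy) for one peptide
transition_fixture <- function() {
  tibble::tibble(
    protein = "sp|P63104|1433Z_HUMAN",
    gene = "YWHAZ",
    peptide_sequence = "VVSSIEQK",
    modified_sequence = rep(c("VVSSIEQK", "VVSSIEQK[+8]"), each = 3),
    isotope_label = rep(c("light", "heavy"), each = 3),
    precursor_mz = rep(c(445.25, 449.26), each = 3),
    precursor_charge = 2L,
    product_mz = c(661.36, 574.33, 487.29, 669.37, 582.34, 495.31),
    collision_energy = 15.2,
    fragment_ion = rep(c("y6", "y5", "y4"), 2)
  )
}

# compact design for tests that do not need the full 390-sample cohort
tiny_design <- function(...) {
  cohort_design(group_sizes = c(Control = 20, AsymAD = 20, AD = 20),
                qc_replicates = 5, ...)
}
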