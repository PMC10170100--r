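# Default peptide panel and cohort design emulating a three-group CSF
# Alzheimer's SRM study: 54 biomarker peptides (from 51-ish proteins), two
# albumin and two hemoglobin peptides monitored for blood contamination, and
# four APOE allele-specific peptides for proteogenomic genotyping.

# genes reported up / down between AT+ and AT- pooled QC standards
.pool_up_genes <- c("YWHAZ", "GDA", "CHI3L1", "PKM", "CALM2", "SMOC1",
                    "YWHAB", "MDH1", "ALDOA", "ENO1", "GOT1", "PPIA",
                    "DDAH1", "PEBP1", "PARK7", "SPP1",
                    "GAPDH", "ENO2", "LDHB", "TPI1", "UCHL1")
.pool_down_genes <- c("PON1", "APOC1", "NPTX2", "VGF", "NPTXR", "SCG2",
                      "CHGA", "CHGB", "SCG3", "NEFL")

#' APOE allele-specific peptides
#'
#' The four tryptic peptides that distinguish ApoE isoforms: CLAVYQAGAR is
#' unique to APOE2, LGADMEDVR to APOE4, LGADMEDVCGR is shared by APOE2 and
#' APOE3, and LAVYQAGAR by APOE3 and APOE4.
#'
#' @return Character vector of the four peptide sequences, in the fixed
#'   reporting order used throughout the package.
#' @export
apoe_peptides <- function() {
  c("CLAVYQAGAR", "LGADMEDVR", "LGADMEDVCGR", "LAVYQAGAR")
}

# which of the four peptides each allele carries
.apoe_allele_map <- list(
  E2 = c("CLAVYQAGAR", "LGADMEDVCGR"),
  E3 = c("LGADMEDVCGR", "LAVYQAGAR"),
  E4 = c("LGADMEDVR", "LAVYQAGAR")
)

apoe_genotypes <- function() {
  c("E2/E2", "E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4")
}

#' Default synthetic peptide panel
#'
#' Builds the 62-peptide panel the cohort generator simulates: 54 biomarker
#' peptides carrying early / progressive / reversing / unchanged abundance
#' trajectories across Control, AsymAD (asymptomatic, biomarker-positive) and
#' AD groups, plus albumin, hemoglobin (HBA/HBB) and APOE allele-specific
#' peptides that are monitored but carry no disease effect. Per-group effects
#' are log2 fold changes relative to Control; `effect_atpos` is the AT+ vs
#' AT- QC-pool effect (21 peptides up, 10 down).
#'
#' @param effect_size Magnitude, in log2 units, of the group effects assigned
#'   to changing peptides (default 0.7).
#' @return Tibble with columns `peptide_id`, `gene`, `role`, `stage`,
#'   `effect_asymad`, `effect_ad`, `effect_atpos`, `baseline`.
#' @export
default_peptide_panel <- function(effect_size = 0.7) {
  stopifnot(is.numeric(effect_size), effect_size >= 0)
  early <- c("SMOC1", "SPP1", "PKM", "MDH1", "ENO1", "ALDOA", "ENO2",
             "LDHB", "TPI1", "GDA", "CHI3L1", "CALM2", "GOT1", "PPIA",
             "DDAH1", "PEBP1", "PARK7", "UCHL1", "GAP43", "BASP1",
             "STMN1", "NRGN")
  progressive <- c("GAPDH", "YWHAB", "YWHAZ")
  reversing <- c("VGF", "NPTX2", "NPTXR", "SCG2", "L1CAM", "CHGA", "CHGB",
                 "SCG3", "APLP1", "NCAM1", "CNTN2", "NELL2", "CPLX1", "SNCB")
  unchanged <- c("PON1", "APOC1", "NEFL", "CLU", "CST3", "APOA1", "TTR",
                 "B2M", "CNDP1", "SERPINA3", "C3", "GSN", "KNG1", "AMBP",
                 "PTGDS")

  e <- effect_size
  biom <- tibble(
    peptide_id = c(early, progressive, reversing, unchanged),
    gene = c(early, progressive, reversing, unchanged),
    role = "biomarker",
    stage = c(rep("early", length(early)),
              rep("progressive", length(progressive)),
              rep("reversing", length(reversing)),
              rep("unchanged", length(unchanged))),
    effect_asymad = c(rep(e, length(early)),
                      rep(e / 2, length(progressive)),
                      rep(e, length(reversing)),
                      rep(0, length(unchanged))),
    effect_ad = c(rep(e, length(early)),
                  rep(e, length(progressive)),
                  rep(0, length(reversing)),
                  rep(0, length(unchanged)))
  )
  monitor <- tibble(
    peptide_id = c("ALB_1", "ALB_2", "HBA", "HBB", apoe_peptides()),
    gene = c("ALB", "ALB", "HBA", "HBB", rep("APOE", 4)),
    role = c("albumin", "albumin", "hemoglobin", "hemoglobin", rep("apoe", 4)),
    stage = "unchanged",
    effect_asymad = 0,
    effect_ad = 0
  )
  panel <- bind_rows(biom, monitor)
  panel$effect_atpos <- dplyr::case_when(
    panel$gene %in% .pool_up_genes ~ e,
    panel$gene %in% .pool_down_genes ~ -e,
    TRUE ~ 0
  )
  panel$baseline <- 1
  panel
}

#' Peptides entering differential-abundance and staging analyses
#'
#' Albumin, hemoglobin and APOE allele-specific peptides are monitored for
#' sample integrity and genotyping, not as disease biomarkers, and are
#' excluded from volcano / staging analyses by their panel role.
#'
#' @param panel A peptide panel tibble (see [default_peptide_panel()]).
#' @return Character vector of biomarker peptide ids.
#' @export
panel_analysis_peptides <- function(panel) {
  panel$peptide_id[panel$role == "biomarker"]
}

# Table-1-style per-group trait distributions (pg/mL; MoCA is a 0-30 score)
default_trait_params <- function() {
  tibble(
    condition = rep(c("Control", "AsymAD", "AD"), each = 4),
    trait = rep(c("moca", "abeta42", "ttau", "ptau"), times = 3),
    mean = c(26.8, 1394.0, 165.8, 14.7,
             26.4, 752.0, 260.8, 25.2,
             17.4, 587.0, 375.7, 38.5),
    sd = c(2.0, 280.7, 35.0, 3.2,
           2.6, 238.2, 97.2, 11.1,
           5.5, 236.8, 139.6, 15.5)
  )
}

# immunoassay values of the pooled QC reference standards
default_pool_traits <- function() {
  tibble(
    pool = c("ATneg", "ATpos"),
    abeta42 = c(1457.3, 482.6),
    ttau = c(172.0, 341.3),
    ptau = c(15.1, 33.1)
  )
}

#' Cohort simulation design
#'
#' Collects every knob of the synthetic-data generator: group sizes, QC
#' replication, the peptide panel with its per-group log2 effects, the noise
#' model (multiplicative lognormal CV on the light/heavy ratio plus
#' independent per-transition area noise), APOE genotype frequencies,
#' blood-contamination spiking, and per-group immunoassay/cognition trait
#' distributions. Defaults emulate a 390-sample cohort (133 Control,
#' 127 AsymAD, 130 AD) with 15-replicate AT- and AT+ QC pools, 12% ratio CV
#' and 5% transition-profile noise.
#'
#' @param group_sizes Named counts for Control/AsymAD/AD.
#' @param qc_replicates Replicate injections per QC pool.
#' @param panel Peptide panel tibble; see [default_peptide_panel()].
#' @param measurement_cv Multiplicative CV (%) on the true light/heavy ratio.
#' @param profile_noise Independent multiplicative noise (%) on each
#'   transition area.
#' @param interference_rate Fraction of rendered light profiles given an
#'   interfering shoulder (see [render_traces()]).
#' @param apoe_frequencies Named genotype probabilities (must sum to 1).
#' @param contamination_fraction Fraction of samples receiving a blood spike.
#' @param contamination_fold Fold increase of hemoglobin-peptide ratios in
#'   spiked samples.
#' @param trait_params Per-group trait mean/sd tibble.
#' @param trait_coupling Tibble (`peptide_id`, `trait`, `rho`) of peptides
#'   whose measurement noise is correlated with a trait's within-group
#'   variation.
#' @param heavy_area Total heavy-standard area per peptide (arbitrary units).
#' @param seed Default RNG seed used when generator functions are not given
#'   one explicitly.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(Control = 133, AsymAD = 127, AD = 130),
                          qc_replicates = 15,
                          panel = default_peptide_panel(),
                          measurement_cv = 12,
                          profile_noise = 5,
                          interference_rate = 0,
                          apoe_frequencies = c("E2/E2" = 0.02, "E2/E3" = 0.10,
                                               "E2/E4" = 0.03, "E3/E3" = 0.55,
                                               "E3/E4" = 0.22, "E4/E4" = 0.08),
                          contamination_fraction = 0.02,
                          contamination_fold = 10,
                          trait_params = default_trait_params(),
                          trait_coupling = tibble(
                            peptide_id = c("SMOC1", "YWHAZ"),
                            trait = c("ttau", "ttau"),
                            rho = c(0.5, 0.5)),
                          heavy_area = 1e5,
                          seed = 1L) {
  design <- list(
    group_sizes = group_sizes, qc_replicates = qc_replicates, panel = panel,
    measurement_cv = measurement_cv, profile_noise = profile_noise,
    interference_rate = interference_rate,
    apoe_frequencies = apoe_frequencies,
    contamination_fraction = contamination_fraction,
    contamination_fold = contamination_fold,
    trait_params = trait_params, trait_coupling = trait_coupling,
    pool_traits = default_pool_traits(),
    heavy_area = heavy_area, seed = seed
  )
  class(design) <- "cohort_design"
  validate_design(design)
}

validate_design <- function(design) {
  gs <- design$group_sizes
  if (is.null(names(gs)) || !all(c("Control", "AsymAD", "AD") %in% names(gs))) {
    abort("group_sizes must be named Control, AsymAD, AD.")
  }
  if (any(gs < 2)) abort("Each group needs at least 2 samples.")
  if (design$qc_replicates < 2) abort("qc_replicates must be at least 2.")
  if (design$measurement_cv < 0 || design$profile_noise < 0) {
    abort("CV parameters must be non-negative.")
  }
  if (abs(sum(design$apoe_frequencies) - 1) > 1e-8) {
    abort("APOE genotype frequencies must sum to 1.")
  }
  if (!all(names(design$apoe_frequencies) %in% apoe_genotypes())) {
    abort("Unknown APOE genotype in apoe_frequencies.")
  }
  if (design$contamination_fraction < 0 || design$contamination_fraction > 1) {
    abort("contamination_fraction must be in [0, 1].")
  }
  if (any(design$panel$baseline <= 0)) abort("Panel baselines must be positive.")
  invisible(design)
}
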