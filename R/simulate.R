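# Synthetic-data generators. These emulate the statistical structure the
# downstream analysis assumes -- lognormal measurement noise on light/heavy
# ratios, matched light/heavy transition profiles with independent area
# noise, group effects in log2 units, Gaussian chromatographic peaks, a
# 10-fold isotopologue dilution ladder, APOE allele dosage, and hemoglobin
# blood spikes -- so that every pipeline stage can be exercised and checked
# against known truth without instrument data.

#' Generate a synthetic three-group CSF cohort
#'
#' Draws per-sample demographics, immunoassay traits (truncated at assay
#' plausibility bounds; amyloid saturates at 1,700 pg/mL), APOE genotypes,
#' and a peptides-by-samples light/heavy ratio matrix. The ratio for sample
#' `s` and peptide `p` is `baseline * 2^effect(group(s))` times a mean-1
#' lognormal factor with CV `measurement_cv`. Peptides listed in the
#' design's `trait_coupling` share noise with the trait's within-group
#' variation at the stated correlation. APOE allele-specific peptide ratios
#' scale with allele dosage and are exactly zero when the genotype lacks the
#' allele. Hemoglobin peptides in a random `contamination_fraction` of
#' samples are multiplied by `contamination_fold`.
#'
#' @param design A [cohort_design()].
#' @param seed RNG seed; defaults to the design's seed. Identical seeds give
#'   bit-identical output.
#' @return List of class `srm_cohort`: `ratios` (peptides x samples tibble,
#'   first column `peptide_id`), `meta` (one row per sample), and `truth`
#'   (list with `expected` per-peptide per-group expected ratios,
#'   `contaminated` sample ids, and the design).
#' @export
generate_cohort <- function(design = cohort_design(), seed = NULL) {
  validate_design(design)
  with_seed(seed %||% design$seed, {
    gs <- design$group_sizes[c("Control", "AsymAD", "AD")]
    n <- sum(gs)
    condition <- rep(names(gs), times = gs)
    sample_id <- sprintf("S%03d", seq_len(n))

    # latent standard-normal draws per trait, reused for trait/peptide coupling
    tp <- design$trait_params
    traits <- unique(tp$trait)
    z <- matrix(stats::rnorm(n * length(traits)), nrow = n,
                dimnames = list(NULL, traits))
    tval <- sapply(traits, function(tr) {
      pars <- tp[tp$trait == tr, ]
      mu <- pars$mean[match(condition, pars$condition)]
      sg <- pars$sd[match(condition, pars$condition)]
      mu + sg * z[, tr]
    })
    moca <- as.integer(pmin(30, pmax(0, round(tval[, "moca"]))))
    abeta42 <- pmin(1700, pmax(100, tval[, "abeta42"]))  # assay saturation cap
    ttau <- pmax(40, tval[, "ttau"])
    ptau <- pmax(2, tval[, "ptau"])

    apoe <- sample(names(design$apoe_frequencies), n, replace = TRUE,
                   prob = design$apoe_frequencies)
    meta <- tibble(
      sample_id = sample_id,
      age = as.integer(pmin(90, pmax(50, round(stats::rnorm(n, 66, 6))))),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.75, 0.25)),
      race = sample(c("White", "Black or African American", "Asian", "Other"),
                    n, replace = TRUE, prob = c(0.7, 0.2, 0.05, 0.05)),
      educ = as.integer(pmin(20, pmax(8, round(stats::rnorm(n, 16, 2.5))))),
      moca = moca,
      apoe = apoe,
      abeta42 = abeta42, ttau = ttau, ptau = ptau,
      ttau_abeta42 = ttau / abeta42,
      run_order = sample.int(n),
      condition = condition
    )

    panel <- design$panel
    sigma <- sdlog_from_cv(design$measurement_cv)
    eff <- cbind(Control = 0, AsymAD = panel$effect_asymad, AD = panel$effect_ad)
    rownames(eff) <- panel$peptide_id

    vals <- matrix(0, nrow = nrow(panel), ncol = n,
                   dimnames = list(panel$peptide_id, sample_id))
    coup <- design$trait_coupling
    for (i in seq_len(nrow(panel))) {
      pid <- panel$peptide_id[i]
      ci <- match(pid, coup$peptide_id)
      zeta <- if (!is.na(ci)) {
        rho <- coup$rho[ci]
        rho * z[, coup$trait[ci]] + sqrt(1 - rho^2) * stats::rnorm(n)
      } else stats::rnorm(n)
      mu_log <- log(panel$baseline[i]) + log(2) * eff[pid, condition] - sigma^2 / 2
      vals[i, ] <- exp(mu_log + sigma * zeta)
    }

    # APOE allele-specific peptides: scale by allele dosage, hard zero when absent
    for (pep in intersect(apoe_peptides(), panel$peptide_id)) {
      scale <- vapply(apoe, function(g) assign_apoe(g)[[pep]], numeric(1)) / 2
      vals[pep, ] <- vals[pep, ] * scale
    }

    ratios <- bind_cols(tibble(peptide_id = panel$peptide_id),
                        as_tibble(vals, .name_repair = "minimal"))

    spiked <- if (design$contamination_fraction > 0) {
      inject_blood_contamination(
        ratios, fraction = design$contamination_fraction,
        fold = design$contamination_fold, seed = NULL
      )
    } else {
      list(ratios = ratios,
           flags = tibble(sample_id = sample_id, contaminated = FALSE))
    }

    expected <- tidyr::expand_grid(peptide_id = panel$peptide_id,
                                   condition = names(gs)) |>
      mutate(expected_ratio = panel$baseline[match(.data$peptide_id, panel$peptide_id)] *
               2^eff[cbind(match(.data$peptide_id, rownames(eff)), match(.data$condition, colnames(eff)))])

    out <- list(
      ratios = spiked$ratios,
      meta = meta,
      truth = list(expected = expected,
                   contaminated = spiked$flags$sample_id[spiked$flags$contaminated],
                   design = design)
    )
    class(out) <- "srm_cohort"
    out
  })
}

#' Generate replicate QC-pool measurements at transition level
#'
#' Simulates `qc_replicates` injections of each pooled CSF reference
#' standard (AT- and AT+). Every peptide has a fixed fractional transition
#' profile shared by its light and heavy labels; the heavy-standard total
#' area is constant per peptide up to a small injection jitter, the light
#' total is `heavy * true_ratio` with lognormal noise at `measurement_cv`,
#' and each of the six transition areas then receives independent
#' multiplicative noise at `profile_noise`. AT+ pool ratios carry the
#' panel's `effect_atpos` log2 effects.
#'
#' @param design A [cohort_design()].
#' @param seed RNG seed (defaults to `design$seed + 1`).
#' @return List: `quants` (one row per replicate x peptide with
#'   `light_1..3`, `heavy_1..3`, `total_area_ratio`, `rdotp`, `rt_apex`,
#'   `true_ratio`) and `meta` (QC sample records with pool immunoassay
#'   values).
#' @export
generate_qc_pools <- function(design = cohort_design(), seed = NULL) {
  validate_design(design)
  with_seed(seed %||% (design$seed + 1L), {
    panel <- design$panel
    npep <- nrow(panel)
    r <- design$qc_replicates

    prof <- matrix(stats::runif(3 * npep, 0.2, 1), nrow = npep)
    prof <- prof / rowSums(prof)
    rt <- seq(1, 13, length.out = npep)

    grid <- tidyr::expand_grid(
      pool = c("ATneg", "ATpos"),
      replicate = seq_len(r),
      idx = seq_len(npep)
    )
    m <- nrow(grid)
    pid <- panel$peptide_id[grid$idx]
    effect <- ifelse(grid$pool == "ATpos", panel$effect_atpos[grid$idx], 0)
    true_ratio <- panel$baseline[grid$idx] * 2^effect
    measured <- true_ratio * rlnorm_cv(m, design$measurement_cv)
    heavy_total <- design$heavy_area * rlnorm_cv(m, 2)
    light_total <- heavy_total * measured

    pn <- design$profile_noise
    light <- light_total * prof[grid$idx, , drop = FALSE] *
      matrix(rlnorm_cv(3 * m, pn), nrow = m)
    heavy <- heavy_total * prof[grid$idx, , drop = FALSE] *
      matrix(rlnorm_cv(3 * m, pn), nrow = m)
    colnames(light) <- paste0("light_", 1:3)
    colnames(heavy) <- paste0("heavy_", 1:3)

    quants <- bind_cols(
      tibble(
        sample_id = ifelse(grid$pool == "ATneg",
                           sprintf("CTL_QC%02d", grid$replicate),
                           sprintf("AD_QC%02d", grid$replicate)),
        pool = grid$pool,
        replicate = grid$replicate,
        peptide_id = pid
      ),
      as_tibble(light), as_tibble(heavy)
    )
    quants$total_area_ratio <- rowSums(light) / rowSums(heavy)
    quants$rdotp <- rowSums(light * heavy) /
      sqrt(rowSums(light^2) * rowSums(heavy^2))
    quants$rt_apex <- rt[grid$idx] + stats::rnorm(m, 0, 0.02)
    quants$true_ratio <- true_ratio

    pt <- design$pool_traits
    meta <- quants |>
      distinct(.data$sample_id, .data$pool) |>
      left_join(pt, by = "pool") |>
      mutate(condition = ifelse(.data$pool == "ATneg", "QC_ATneg", "QC_ATpos"),
             ttau_abeta42 = .data$ttau / .data$abeta42,
             moca = NA_integer_) |>
      select(-"pool")
    list(quants = quants, meta = meta)
  })
}

#' Render Gaussian chromatogram traces for quantified transitions
#'
#' Turns stored transition areas back into time/intensity traces: each
#' transition becomes a Gaussian peak centred at the peptide's retention
#' apex whose integral equals the stored area (to well within 1% on the
#' default grid), on an optional constant baseline with additive noise.
#' Light and heavy transitions co-elute. With `interference_rate > 0`, a
#' random subset of peptide profiles gains an interfering shoulder on the
#' first light transition only, which depresses the downstream ratio
#' dot product.
#'
#' @param quants Tibble with `sample_id`, `peptide_id`, `rt_apex` and
#'   `light_1..3` / `heavy_1..3` area columns (see [generate_qc_pools()]).
#' @param peak_sigma Gaussian peak SD in minutes.
#' @param dt Grid spacing in minutes.
#' @param gradient Two-element vector, the LC gradient window in minutes.
#' @param baseline_level,baseline_noise Constant baseline intensity and the
#'   SD of additive noise on it.
#' @param interference_rate Fraction of rows whose light profile is
#'   distorted by a shoulder peak.
#' @param interference_scale Area of the shoulder relative to the parent
#'   transition.
#' @param seed RNG seed for baseline noise and interference assignment.
#' @return Long tibble: `sample_id`, `peptide_id`, `label`, `transition`,
#'   `time`, `intensity`, `interfered`.
#' @export
render_traces <- function(quants, peak_sigma = 0.05, dt = 0.005,
                          gradient = c(0, 14),
                          baseline_level = 0, baseline_noise = 0,
                          interference_rate = 0, interference_scale = 0.5,
                          seed = 1L) {
  stopifnot(peak_sigma > 0, dt > 0)
  if (any(quants$rt_apex < gradient[1] | quants$rt_apex > gradient[2])) {
    abort("rt_apex outside the gradient window.")
  }
  with_seed(seed, {
    interfered <- stats::runif(nrow(quants)) < interference_rate
    rows <- purrr::map(seq_len(nrow(quants)), function(i) {
      q <- quants[i, ]
      tgrid <- seq(max(gradient[1], q$rt_apex - 6 * peak_sigma),
                   min(gradient[2], q$rt_apex + 6 * peak_sigma), by = dt)
      purrr::map2_dfr(
        rep(c("light", "heavy"), each = 3), rep(1:3, times = 2),
        function(lab, k) {
          area <- q[[paste0(lab, "_", k)]]
          intensity <- area * stats::dnorm(tgrid, q$rt_apex, peak_sigma)
          if (interfered[i] && lab == "light" && k == 1) {
            intensity <- intensity + interference_scale * area *
              stats::dnorm(tgrid, q$rt_apex + 1.5 * peak_sigma, peak_sigma)
          }
          if (baseline_level > 0 || baseline_noise > 0) {
            intensity <- pmax(0, intensity + baseline_level +
                                stats::rnorm(length(tgrid), 0, baseline_noise))
          }
          tibble(sample_id = q$sample_id, peptide_id = q$peptide_id,
                 label = lab, transition = k, time = tgrid,
                 intensity = intensity, interfered = interfered[i] && lab == "light" && k == 1)
        })
    })
    bind_rows(rows)
  })
}

#' Generate an isotopologue dilution ladder
#'
#' Simulates a six-peptide reference mix spiked as five 10-fold dilutions
#' (1 pmol, 100 fmol, 10 fmol, 1 fmol, 100 amol per injection). Observed
#' areas are proportional to amount with multiplicative noise, plus
#' additive baseline noise that dominates at the lowest level, so that the
#' 100-amol rung falls below the detection floor and the 1-fmol rung shows
#' an elevated label-free CV.
#'
#' @param n_injections Injections per level.
#' @param noise_floor Detection floor in area units: a level whose mean raw
#'   area is at or below this is called not-detected.
#' @param response Per-peptide response factors (area units per fmol).
#' @param area_cv Multiplicative CV (%) on each raw area.
#' @param additive_sd SD of additive baseline noise (area units).
#' @param seed RNG seed.
#' @return List of class `dilution_series`: `areas` (tibble `peptide_id`,
#'   `amount_fmol`, `injection`, `area`), `levels_fmol`, `noise_floor`.
#' @export
generate_dilution_series <- function(n_injections = 20, noise_floor = 500,
                                     response = c(1500, 1900, 2300, 1700, 2500, 2100),
                                     area_cv = 10, additive_sd = 200,
                                     seed = 1L) {
  stopifnot(n_injections >= 2, length(response) == 6, all(response > 0))
  levels_fmol <- c(1000, 100, 10, 1, 0.1)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      peptide_id = sprintf("ISOPEP_%d", 1:6),
      amount_fmol = levels_fmol,
      injection = seq_len(n_injections)
    )
    k <- response[as.integer(sub("ISOPEP_", "", grid$peptide_id))]
    true <- k * grid$amount_fmol
    grid$area <- pmax(0, true * rlnorm_cv(nrow(grid), area_cv) +
                        stats::rnorm(nrow(grid), 0, additive_sd))
    out <- list(areas = grid, levels_fmol = levels_fmol,
                noise_floor = noise_floor)
    class(out) <- "dilution_series"
    out
  })
}

#' APOE allele dosage of the four allele-specific peptides
#'
#' Maps a six-genotype APOE genotype to the number of alleles (0, 1 or 2)
#' carrying each allele-specific peptide: CLAVYQAGAR is borne by the E2
#' allele, LGADMEDVR by E4, LGADMEDVCGR by E2 and E3, and LAVYQAGAR by E3
#' and E4. A zero dosage implies a true-zero ratio in the data matrix.
#'
#' @param genotype One of `"E2/E2"`, `"E2/E3"`, `"E2/E4"`, `"E3/E3"`,
#'   `"E3/E4"`, `"E4/E4"`.
#' @return Named numeric vector of allele counts for the four peptides.
#' @export
assign_apoe <- function(genotype) {
  if (!is.character(genotype) || length(genotype) != 1 ||
      !genotype %in% apoe_genotypes()) {
    abort(sprintf("Unknown APOE genotype; expected one of %s.",
                  paste(apoe_genotypes(), collapse = ", ")))
  }
  alleles <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  counts <- setNames(numeric(4), apoe_peptides())
  for (a in alleles) counts[.apoe_allele_map[[a]]] <- counts[.apoe_allele_map[[a]]] + 1
  counts
}

#' Spike hemoglobin peptides to emulate blood contamination
#'
#' Multiplies the HBA/HBB rows of a ratio matrix by `fold` in a random
#' Bernoulli(`fraction`) subset of samples, leaving every other peptide
#' untouched, and returns the truth flags alongside the spiked matrix.
#'
#' @param ratios Ratio matrix tibble (`peptide_id` + sample columns).
#' @param fraction Probability that a sample is contaminated.
#' @param fold Fold increase applied to hemoglobin ratios.
#' @param hb_peptides Ids of the hemoglobin rows.
#' @param seed RNG seed; `NULL` draws from the current RNG stream.
#' @return List: `ratios` (spiked matrix) and `flags` (tibble `sample_id`,
#'   `contaminated`).
#' @export
inject_blood_contamination <- function(ratios, fraction = 0.02, fold = 10,
                                       hb_peptides = c("HBA", "HBB"),
                                       seed = NULL) {
  assert_ratio_matrix(ratios)
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1].")
  if (!all(hb_peptides %in% ratios$peptide_id)) {
    abort("Hemoglobin peptides missing from the ratio matrix.")
  }
  run <- function() {
    samples <- setdiff(names(ratios), "peptide_id")
    hit <- stats::rbinom(length(samples), 1, fraction) == 1
    rows <- ratios$peptide_id %in% hb_peptides
    for (j in which(hit)) {
      ratios[rows, samples[j]] <- ratios[rows, samples[j]] * fold
    }
    list(ratios = ratios, flags = tibble(sample_id = samples, contaminated = hit))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
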