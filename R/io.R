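# Readers and writers for the three deposited CSV layouts: the transition
# list, the peptides-by-samples ratio data matrix, and the sample metadata.
# Comma-separated, UTF-8, "." decimal; ratios serialised with 6 significant
# digits. Empty cells encode not-available trait values on disk and become
# NA in memory; zero is never a missing marker (a zero ratio means the
# APOE allele-specific peptide is biologically absent).

transition_columns <- c("protein", "gene", "peptide_sequence",
                        "modified_sequence", "isotope_label",
                        "precursor_mz", "precursor_charge", "product_mz",
                        "collision_energy", "fragment_ion")

metadata_columns <- c("sample_id", "age", "sex", "race", "educ", "moca",
                      "apoe", "abeta42", "ttau", "ptau", "ttau_abeta42",
                      "run_order", "condition")

condition_levels <- c("Control", "AsymAD", "AD", "QC_ATneg", "QC_ATpos")

#' Read a transition list CSV
#'
#' Parses the ten-column transition layout (protein, gene, peptide and
#' modified sequences, isotope label, precursor m/z and charge, product
#' m/z, collision energy, fragment ion), assigns a `peptide_id` linking
#' light and heavy rows of the same peptide sequence, and warns about
#' heavy precursors that lack a light partner (or vice versa).
#'
#' @param path CSV file path.
#' @return Tibble of transition records with a `peptide_id` column.
#' @export
read_transition_list <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    protein = readr::col_character(),
    gene = readr::col_character(),
    peptide_sequence = readr::col_character(),
    modified_sequence = readr::col_character(),
    isotope_label = readr::col_character(),
    precursor_mz = readr::col_double(),
    precursor_charge = readr::col_integer(),
    product_mz = readr::col_double(),
    collision_energy = readr::col_double(),
    fragment_ion = readr::col_character()
  ), show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(transition_columns, names(tr))
  if (length(missing)) {
    abort(sprintf("Transition list is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(tr)
  if (nrow(probs)) {
    abort(sprintf("Malformed transition value(s), e.g. line %d: expected %s.",
                  probs$row[1], probs$expected[1]))
  }
  if (nrow(tr) == 0) return(mutate(tr, peptide_id = character(0)))
  if (!all(tr$isotope_label %in% c("light", "heavy"))) {
    abort("isotope_label must be 'light' or 'heavy'.")
  }
  tr$peptide_id <- tr$peptide_sequence
  labsets <- tr |>
    distinct(.data$peptide_id, .data$isotope_label) |>
    dplyr::count(.data$peptide_id)
  orphans <- labsets$peptide_id[labsets$n < 2]
  if (length(orphans)) {
    warn(sprintf("Unpaired precursors (only one isotope label present): %s.",
                 paste(orphans, collapse = ", ")))
  }
  tr
}

#' Write a transition list CSV
#'
#' @param transitions Tibble with the ten transition columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_transition_list <- function(transitions, path) {
  missing <- setdiff(transition_columns, names(transitions))
  if (length(missing)) {
    abort(sprintf("Missing transition column(s): %s.", paste(missing, collapse = ", ")))
  }
  readr::write_csv(transitions[transition_columns], path, progress = FALSE)
  invisible(path)
}

#' Write a peptide ratio data matrix CSV
#'
#' First column holds the peptide ids, one column per sample; ratios are
#' serialised with 6 significant digits and round-trip with
#' [read_ratio_matrix()] at that precision. Zeros are written as `0`,
#' never as blanks; negative or missing cells are refused.
#'
#' @param ratios Ratio matrix tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ratio_matrix <- function(ratios, path) {
  assert_ratio_matrix(ratios)
  out <- ratios |>
    mutate(across(-"peptide_id", ~ signif(.x, 6)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a peptide ratio data matrix CSV
#'
#' @param path CSV path written by [write_ratio_matrix()] (or any layout
#'   with a peptide id first column and unique sample columns).
#' @return Validated ratio matrix tibble.
#' @export
read_ratio_matrix <- function(path) {
  ratios <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            name_repair = "minimal")
  names(ratios)[1] <- "peptide_id"
  assert_ratio_matrix(ratios)
  ratios
}

#' Read sample metadata CSV
#'
#' Parses the trait layout (sample id, age, sex, race, education, MoCA,
#' APOE genotype, the three immunoassay values, the tTau/amyloid ratio,
#' run order, condition). Blank immunoassay or MoCA cells become `NA`;
#' conditions are restricted to Control/AsymAD/AD/QC_ATneg/QC_ATpos; MoCA
#' must lie in 0-30 and run orders must be unique.
#'
#' @param path CSV path.
#' @return Tibble of sample records.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    race = readr::col_character(),
    educ = readr::col_integer(),
    moca = readr::col_integer(),
    apoe = readr::col_character(),
    abeta42 = readr::col_double(),
    ttau = readr::col_double(),
    ptau = readr::col_double(),
    ttau_abeta42 = readr::col_double(),
    run_order = readr::col_integer(),
    condition = readr::col_character()
  ), show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(metadata_columns, names(meta))
  if (length(missing)) {
    abort(sprintf("Sample metadata is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(meta$condition), condition_levels)
  if (length(bad)) {
    abort(sprintf("Unknown condition label(s) %s; allowed: %s.",
                  paste(bad, collapse = ", "),
                  paste(condition_levels, collapse = ", ")))
  }
  if (any(!is.na(meta$moca) & (meta$moca < 0 | meta$moca > 30))) {
    abort("MoCA scores must lie in 0-30.")
  }
  ro <- meta$run_order[!is.na(meta$run_order)]
  if (anyDuplicated(ro)) abort("run_order values must be unique.")
  meta
}

#' Write sample metadata CSV
#'
#' Not-available traits are written as empty cells (never zeros).
#'
#' @param meta Sample metadata tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  missing <- setdiff(metadata_columns, names(meta))
  if (length(missing)) {
    abort(sprintf("Missing metadata column(s): %s.", paste(missing, collapse = ", ")))
  }
  readr::write_csv(meta[metadata_columns], path, na = "", progress = FALSE)
  invisible(path)
}
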