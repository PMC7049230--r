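#' @keywords internal
#' @noRd
lfq_cols <- function(quant) {
  names(quant)[startsWith(names(quant), "lfq_")]
}

#' @keywords internal
#' @noRd
ibaq_cols <- function(quant) {
  names(quant)[startsWith(names(quant), "ibaq_")]
}

# "identified" = nonmissing, nonzero LFQ intensity; MaxQuant writes 0 for
# not-quantified, so 0 and NA both count as missing.
#' @keywords internal
#' @noRd
lfq_present <- function(x) {
  !is.na(x) & x > 0
}

check_design_covers <- function(quant, design) {
  samples <- sub("^lfq_", "", lfq_cols(quant))
  missing_d <- setdiff(samples, design$sample_id)
  if (length(missing_d) > 0) {
    abort(paste0("design does not cover sample(s): ", paste(missing_d, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Remove quality-control-flagged protein groups
#'
#' Drops reverse (decoy) hits, potential contaminants and proteins only
#' identified by a modification site — the standard identification-level
#' clean-up applied to search-engine output before any quantitative analysis.
#' Flag columns absent from the table are treated as all-false with a
#' warning; row order is preserved.
#'
#' @param quant Protein quantification tibble with logical columns
#'   `reverse`, `contaminant`, `only_site` (see [simulate_ms_dataset()] or
#'   [read_maxquant()]).
#' @return The tibble with flagged rows removed.
#' @export
filter_qc_flags <- function(quant) {
  flags <- c("reverse", "contaminant", "only_site")
  absent <- setdiff(flags, names(quant))
  if (length(absent) > 0) {
    warn(paste0("flag column(s) missing, treated as all-false: ",
                paste(absent, collapse = ", ")))
    for (f in absent) quant[[f]] <- FALSE
  }
  bad <- purrr::reduce(purrr::map(flags, ~ isTRUE_vec(quant[[.x]])), `|`)
  quant[!bad, , drop = FALSE]
}

#' @keywords internal
#' @noRd
isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x else !is.na(x) & x %in% c("+", "TRUE", "yes")
}

#' Keep proteins reproducibly identified within at least one group
#'
#' A protein passes when there is at least one non-exclusion group in which
#' every replicate has a nonmissing, nonzero LFQ intensity — the
#' identify-in-all-replicates-of-some-group rule that guards against
#' one-off identifications.
#'
#' @param quant Protein quantification tibble.
#' @param design Experiment design tibble (`sample_id`, `group_id`,
#'   `exclusion`, ...).
#' @return The tibble restricted to presence-passing proteins.
#' @export
filter_replicate_presence <- function(quant, design) {
  check_design_covers(quant, design)
  groups <- design %>% dplyr::filter(!.data$exclusion)
  if (nrow(groups) == 0) abort("design has no non-exclusion groups")
  split_samples <- split(groups$sample_id, groups$group_id)
  if (any(lengths(split_samples) == 0)) abort("a group has zero replicates")
  keep <- rep(FALSE, nrow(quant))
  for (samp in split_samples) {
    cols <- paste0("lfq_", samp)
    pres <- vapply(cols, function(cn) lfq_present(quant[[cn]]), logical(nrow(quant)))
    pres <- matrix(pres, nrow = nrow(quant))
    keep <- keep | rowSums(pres) == length(cols)
  }
  quant[keep, , drop = FALSE]
}

#' Exclude proteins detected in any negative or mock control
#'
#' Any protein with a nonmissing quantification in any sample of any
#' exclusion group (bead-only negative controls, buffer-only mock controls)
#' is treated as background binding and removed from the candidate set.
#'
#' @inheritParams filter_replicate_presence
#' @return The tibble restricted to proteins never seen in controls.
#' @export
filter_control_exclusion <- function(quant, design) {
  check_design_covers(quant, design)
  excl_samples <- design$sample_id[design$exclusion]
  if (length(excl_samples) == 0) {
    return(quant)
  }
  cols <- paste0("lfq_", excl_samples)
  cols <- intersect(cols, names(quant))
  if (length(cols) == 0) {
    return(quant)
  }
  pres <- vapply(cols, function(cn) lfq_present(quant[[cn]]), logical(nrow(quant)))
  pres <- matrix(pres, nrow = nrow(quant))
  quant[rowSums(pres) == 0, , drop = FALSE]
}

#' Canonical identification-filter chain
#'
#' QC-flag removal, then replicate-presence, then control exclusion — the
#' order used throughout this package. Each step shrinks the row set.
#'
#' @inheritParams filter_replicate_presence
#' @return Filtered tibble of candidate autoantigens.
#' @export
filter_candidates <- function(quant, design) {
  quant %>%
    filter_qc_flags() %>%
    filter_replicate_presence(design) %>%
    filter_control_exclusion(design)
}

#' Antigens identified in one experimental group
#'
#' Proteins with complete quantification across all replicates of the named
#' group, sorted by descending mean LFQ intensity (ties broken by
#' accession), i.e. the per-group antigen list of a capture experiment.
#'
#' @inheritParams filter_replicate_presence
#' @param group_id Single group label present in `design`.
#' @return Character vector of protein ids.
#' @export
group_antigens <- function(quant, design, group_id) {
  if (!group_id %in% design$group_id) {
    abort(paste0("unknown group: ", group_id))
  }
  samp <- design$sample_id[design$group_id == group_id]
  cols <- paste0("lfq_", samp)
  pres <- vapply(cols, function(cn) lfq_present(quant[[cn]]), logical(nrow(quant)))
  pres <- matrix(pres, nrow = nrow(quant))
  complete <- rowSums(pres) == length(cols)
  sub <- quant[complete, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(character(0))
  }
  mean_int <- rowMeans(as.matrix(sub[cols]))
  sub$protein_id[order(-mean_int, sub$protein_id)]
}

#' iBAQ relative-abundance fractions within a group
#'
#' For each protein identified in the group, the mean iBAQ intensity over
#' the group's replicates is expressed as a percentage of the group total.
#' iBAQ is proportional to molar amount, so these fractions estimate the
#' molar share each captured antigen contributes — the natural readout for
#' ranking an autoantibody repertoire by abundance.
#'
#' @inheritParams group_antigens
#' @param protein_ids Optional restriction to these proteins; defaults to
#'   [group_antigens()] of the group.
#' @return Tibble with `protein_id`, `mean_ibaq`, `ibaq_fraction`
#'   (percent, summing to 100), sorted descending.
#' @export
#' @examples
#' sim <- simulate_ms_dataset(ms_sim_config(n_proteins = 30, seed = 2))
#' head(ibaq_fractions(sim$quant, sim$design, "CH"))
ibaq_fractions <- function(quant, design, group_id, protein_ids = NULL) {
  if (is.null(protein_ids)) {
    protein_ids <- group_antigens(quant, design, group_id)
  }
  samp <- design$sample_id[design$group_id == group_id]
  cols <- paste0("ibaq_", samp)
  cols <- intersect(cols, names(quant))
  if (length(cols) == 0) abort("no iBAQ columns for this group")
  sub <- quant[quant$protein_id %in% protein_ids, , drop = FALSE]
  m <- as.matrix(sub[cols])
  m[m == 0] <- NA_real_
  mean_ibaq <- rowMeans(m, na.rm = TRUE)
  mean_ibaq[is.nan(mean_ibaq)] <- NA_real_
  if (all(is.na(mean_ibaq)) || sum(mean_ibaq, na.rm = TRUE) <= 0) {
    abort("all iBAQ intensities are missing or zero for this group")
  }
  mean_ibaq[is.na(mean_ibaq)] <- 0
  tibble::tibble(
    protein_id = sub$protein_id,
    mean_ibaq = mean_ibaq,
    ibaq_fraction = 100 * mean_ibaq / sum(mean_ibaq)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$ibaq_fraction), .data$protein_id)
}
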