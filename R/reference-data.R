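#' Packaged published summary tables
#'
#' Small reference tables shipped with the package, typed in from the
#' published summary statistics of a glaucoma autoantibody study; they
#' serve as worked-example inputs for the arithmetic this package
#' implements:
#'
#' * `"htm_ctrl_ibaq"` — iBAQ percentages of the 66 autoantigens captured
#'   from healthy trabecular-meshwork lysate by control-serum IgG
#'   (`entry_name`, `accession`, `ibaq_pct`).
#' * `"microarray_rank_sums"` — Mann-Whitney summary of the 6-target
#'   microarray validation at n = 120 vs 120 (rank sums per group and the
#'   printed U / Z / tie-adjusted Z).
#' * `"clinical_spearman"` — Spearman correlations of four autoantibody
#'   levels with cup-disc ratio, visual-field mean deviation and
#'   intraocular pressure (`valid_n`, printed R, t and p).
#' * `"candidate_volcano"` — the 21 differential candidates' printed
#'   (-log10 p, log2 difference) pairs.
#'
#' @param name One of the table names above.
#' @return A tibble.
#' @export
#' @examples
#' head(reference_table("microarray_rank_sums"))
reference_table <- function(name = c("htm_ctrl_ibaq", "microarray_rank_sums",
                                     "clinical_spearman", "candidate_volcano")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "seroscreen",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
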