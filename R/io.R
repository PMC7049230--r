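#' Default MaxQuant-dialect column mapping
#'
#' Maps the internal column names onto the headers of a proteinGroups
#' export. Override entries to read other dialects.
#'
#' @return Named character vector (internal name -> file header).
#' @export
maxquant_columns <- function() {
  c(
    protein_id = "Majority protein IDs",
    entry_name = "Protein names",
    reverse = "Reverse",
    contaminant = "Potential contaminant",
    only_site = "Only identified by site",
    lfq_prefix = "LFQ intensity ",
    ibaq_prefix = "iBAQ "
  )
}

#' Read a protein-group quantification TSV
#'
#' Reads a MaxQuant-dialect proteinGroups table: flag columns marked with
#' `"+"` become logicals, per-sample intensity columns are detected by
#' prefix, and zero intensities are mapped to missing (MaxQuant writes 0
#' for not-quantified).
#'
#' @param path TSV file path.
#' @param columns Column mapping as from [maxquant_columns()].
#' @return Quantification tibble in the internal layout (`protein_id`,
#'   `entry_name`, flags, `lfq_*`, `ibaq_*`).
#' @export
read_maxquant <- function(path, columns = maxquant_columns()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    protein_id = as.character(raw[[columns[["protein_id"]]]]),
    entry_name = if (columns[["entry_name"]] %in% names(raw)) {
      as.character(raw[[columns[["entry_name"]]]])
    } else {
      NA_character_
    }
  )
  for (f in c("reverse", "contaminant", "only_site")) {
    cn <- columns[[f]]
    out[[f]] <- if (cn %in% names(raw)) isTRUE_vec(raw[[cn]]) else FALSE
  }
  for (kind in c("lfq", "ibaq")) {
    prefix <- columns[[paste0(kind, "_prefix")]]
    cols <- names(raw)[startsWith(names(raw), prefix)]
    for (cn in cols) {
      samp <- substring(cn, nchar(prefix) + 1)
      v <- as.numeric(raw[[cn]])
      v[v == 0] <- NA_real_
      out[[paste0(kind, "_", samp)]] <- v
    }
  }
  out
}

#' Write a quantification tibble as MaxQuant-dialect TSV
#'
#' @param quant Internal-layout quantification tibble.
#' @param path Output TSV path.
#' @param columns Column mapping as from [maxquant_columns()].
#' @return `path`, invisibly.
#' @export
write_maxquant <- function(quant, path, columns = maxquant_columns()) {
  out <- tibble::tibble(!!columns[["protein_id"]] := quant$protein_id)
  out[[columns[["entry_name"]]]] <- quant$entry_name
  for (f in c("reverse", "contaminant", "only_site")) {
    out[[columns[[f]]]] <- ifelse(isTRUE_vec(quant[[f]]), "+", "")
  }
  for (cn in names(quant)) {
    if (startsWith(cn, "lfq_")) {
      v <- quant[[cn]]
      v[is.na(v)] <- 0
      out[[paste0(columns[["lfq_prefix"]], sub("^lfq_", "", cn))]] <- v
    } else if (startsWith(cn, "ibaq_")) {
      v <- quant[[cn]]
      v[is.na(v)] <- 0
      out[[paste0(columns[["ibaq_prefix"]], sub("^ibaq_", "", cn))]] <- v
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a spot table as annotated TSV
#'
#' GPR-style export: a small `#`-prefixed header block (key=value) followed
#' by the tab-separated spot records.
#'
#' @param spots Spot tibble.
#' @param path Output path.
#' @param header Named character vector written into the header block.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path, header = c(type = "seroscreen spot table")) {
  lines <- paste0("# ", names(header), "=", header)
  writeLines(lines, path)
  con <- file(path, "ab")
  on.exit(close(con))
  readr::write_tsv(spots, con, progress = FALSE)
  invisible(path)
}

#' Read an annotated spot-table TSV
#'
#' Counterpart of [write_spot_table()]; also accepts plain TSV without a
#' header block. A column mapping renames file headers onto the internal
#' names (`slide_id`, `subarray_id`, `block`, `row`, `column`,
#' `target_id`, `spot_role`, `replicate_index`, `foreground`,
#' `local_background`, `flag`, `sample_id`).
#'
#' @param path File path.
#' @param columns Optional named character vector (internal -> file header).
#' @return Spot tibble.
#' @export
read_spot_table <- function(path, columns = NULL) {
  spots <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(columns)) {
    for (internal in names(columns)) {
      if (columns[[internal]] %in% names(spots)) {
        names(spots)[names(spots) == columns[[internal]]] <- internal
      }
    }
  }
  spots
}

#' Write an NFI matrix with its normalization record
#'
#' Writes the samples x targets table as TSV; the per-subarray
#' normalization factors and the stage audit, when present, go to sidecar
#' TSVs (`<path>.factors.tsv`, `<path>.audit.tsv`).
#'
#' @param nfi `nfi_matrix` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_nfi <- function(nfi, path) {
  readr::write_tsv(tibble::as_tibble(nfi), path, progress = FALSE)
  nf <- norm_factors(nfi)
  if (!is.null(nf)) {
    readr::write_tsv(nf, paste0(path, ".factors.tsv"), progress = FALSE)
  }
  audit <- preprocess_audit(nfi)
  if (!is.null(audit)) {
    readr::write_tsv(audit, paste0(path, ".audit.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' Read an NFI matrix TSV
#'
#' @param path TSV written by [write_nfi()] (sidecars optional).
#' @return `nfi_matrix` tibble.
#' @export
read_nfi <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nf <- if (file.exists(paste0(path, ".factors.tsv"))) {
    readr::read_tsv(paste0(path, ".factors.tsv"), show_col_types = FALSE,
                    progress = FALSE)
  }
  audit <- if (file.exists(paste0(path, ".audit.tsv"))) {
    readr::read_tsv(paste0(path, ".audit.tsv"), show_col_types = FALSE,
                    progress = FALSE)
  }
  new_nfi_matrix(wide, norm_factors = nf, audit = audit)
}
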