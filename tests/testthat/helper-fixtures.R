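# Small programmatic fixtures shared across test files.

# Minimal design: one exclusion group NC (1 replicate), experimental
# groups A and B (n_rep replicates each).
tiny_design <- function(n_rep = 3) {
  rows <- list(
    list("NC", "none", "HTM", 1L, TRUE),
    list("A", "CTRL", "HTM", as.integer(n_rep), FALSE),
    list("B", "CTRL", "GTM", as.integer(n_rep), FALSE)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      sample_id = paste0(r[[1]], "_", seq_len(r[[4]])),
      group_id = r[[1]], replicate_index = seq_len(r[[4]]),
      igg_source = r[[2]], protein_source = r[[3]], exclusion = r[[5]],
      stringsAsFactors = FALSE
    )
  }))
  tibble::as_tibble(out)
}

# Build a quant tibble from a named list protein_id -> named numeric vector
# of LFQ intensities (samples absent from the vector are missing).
make_quant <- function(intensities, design, flags = NULL) {
  ids <- names(intensities)
  quant <- tibble::tibble(
    protein_id = ids,
    entry_name = paste0(ids, "_HUMAN"),
    reverse = FALSE, contaminant = FALSE, only_site = FALSE
  )
  if (!is.null(flags)) {
    for (f in names(flags)) quant[[f]] <- flags[[f]]
  }
  for (s in design$sample_id) {
    quant[[paste0("lfq_", s)]] <-
      vapply(intensities, function(v) {
        if (s %in% names(v)) unname(v[[s]]) else NA_real_
      }, numeric(1))
    quant[[paste0("ibaq_", s)]] <- quant[[paste0("lfq_", s)]] / 10
  }
  quant
}

# Spot tibble for hand-built preprocessing cases: one row per spot; grid
# coordinates are assigned uniquely within each subarray.
make_spots <- function(df) {
  defaults <- list(
    slide_id = "S01", subarray_id = 1L, sample_id = "X1",
    block = 1L, target_id = "T01", spot_role = "antigen",
    replicate_index = 1L, foreground = 1000, local_background = 0,
    flag = "ok"
  )
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cn in names(defaults)) {
    if (!cn %in% names(out)) out[[cn]] <- defaults[[cn]]
  }
  key <- paste(out$slide_id, out$subarray_id)
  out$row <- stats::ave(seq_len(nrow(out)), key, FUN = seq_along)
  out$column <- 1L
  tibble::as_tibble(out)
}

# Reference Mann-Whitney U by brute-force pair counting.
brute_u <- function(x, y) {
  u1 <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(u1, length(x) * length(y) - u1)
}
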