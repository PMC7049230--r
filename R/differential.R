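#' Log2 intensity matrix from a quantification table
#'
#' Extracts the LFQ columns of selected samples as a proteins x samples
#' matrix on the log2 scale, with zeros treated as missing.
#'
#' @param quant Protein quantification tibble.
#' @param design Experiment design tibble.
#' @param samples Sample ids to include; default all in `design`.
#' @return Numeric matrix, rownames = protein ids, colnames = sample ids.
#' @export
log2_intensity_matrix <- function(quant, design, samples = design$sample_id) {
  cols <- paste0("lfq_", samples)
  missing_c <- setdiff(cols, names(quant))
  if (length(missing_c) > 0) {
    abort(paste0("quant table lacks column(s): ", paste(missing_c, collapse = ", ")))
  }
  m <- as.matrix(quant[cols])
  m[m <= 0] <- NA_real_
  m <- log2(m)
  dimnames(m) <- list(quant$protein_id, samples)
  m
}

#' Gaussian down-shift imputation of missing intensities
#'
#' Missing cells in a log2 intensity matrix are drawn from a normal
#' distribution shrunk and shifted relative to each sample's observed
#' distribution: `N(mean_s - shift * sd_s, (width * sd_s)^2)`. This models
#' left-censored missingness — values are missing because they fell below
#' the detection limit, so plausible replacements sit in the lower tail of
#' the observed distribution. Statistics are per sample (column-wise).
#'
#' @param mat Proteins x samples numeric matrix on log2 scale (may contain
#'   `NA`), or a tibble with a `protein_id` column and sample columns.
#' @param width Width of the imputation distribution, as a multiple of the
#'   sample SD (default 0.3).
#' @param shift Down-shift in sample SDs (default 1.8).
#' @param seed Integer seed; imputation is deterministic given it.
#' @return Object of the same shape with no missing values; observed cells
#'   are untouched.
#' @export
impute_downshift <- function(mat, width = 0.3, shift = 1.8, seed = 1L) {
  tib <- NULL
  if (is.data.frame(mat)) {
    tib <- mat
    mat <- as.matrix(tib[setdiff(names(tib), "protein_id")])
    rownames(mat) <- tib$protein_id
  }
  stopifnot(is.matrix(mat))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    miss <- which(is.na(mat[, j]))
    if (length(miss) == 0) next
    if (length(obs) < 2) {
      abort(sprintf("sample %s has fewer than 2 observed values; cannot impute",
                    colnames(mat)[j] %||% j))
    }
    mu <- mean(obs)
    s <- stats::sd(obs)
    mat[miss, j] <- rnorm(length(miss), mean = mu - shift * s, sd = width * s)
  }
  if (!is.null(tib)) {
    out <- tibble::as_tibble(mat, .name_repair = "minimal")
    out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)), out)
    return(out)
  }
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
two_sample_t <- function(mat, idx1, idx2, s0 = 0) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- (rowSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(x2^2) - n2 * m2^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- m2 - m1
  t <- diff / (se + s0)
  list(difference = diff, t = t, df = n1 + n2 - 2)
}

#' Permutation-FDR two-sample t-test on log2 intensities
#'
#' Student's pooled-variance t-test per protein with a permutation-based
#' false discovery rate in the SAM/Perseus style: group labels are permuted
#' (all distinct splits when few, otherwise a uniform subsample without
#' replacement), null statistics are pooled across proteins, and
#' `q(protein)` is the median over permutations of the number of null
#' `|t|` values at least as extreme as the protein's, divided by the number
#' of observed `|t|` at least as extreme, clipped to `[0, 1]` and
#' monotonized along the `|t|` ranking. An optional fudge factor `s0` is
#' added to the standard error to damp low-variance artefacts.
#'
#' @param mat Proteins x samples log2 matrix without missing values (impute
#'   first with [impute_downshift()]), or tibble with `protein_id`.
#' @param design Experiment design tibble.
#' @param group1,group2 Group labels to compare; the reported `difference`
#'   is mean(group2) - mean(group1).
#' @param n_permutations Maximum number of label permutations (default 250).
#' @param seed Integer seed for the permutation subsample.
#' @param s0 Fudge factor added to the pooled standard error (default 0).
#' @param fdr_threshold,fc_threshold Selection thresholds recorded in the
#'   result (`passes_selection` is `q < fdr_threshold & |difference| >
#'   fc_threshold`).
#' @return Object of class `perm_fdr_test`; use [tidy()] for the per-protein
#'   table (`protein_id`, `difference`, `t_stat`, `p_value`, `q_value`,
#'   `neg_log10_p`, `passes_selection`) and [glance()] for a one-row summary.
#' @export
#' @examples
#' sim <- simulate_ms_dataset(ms_sim_config(n_proteins = 60, seed = 5))
#' filt <- filter_candidates(sim$quant, sim$design)
#' m <- log2_intensity_matrix(filt, sim$design,
#'                            sim$design$sample_id[sim$design$group_id %in% c("CH", "CG")])
#' m <- impute_downshift(m, seed = 5)
#' fit <- permutation_fdr_ttest(m, sim$design, "CH", "CG", seed = 5)
#' head(tidy(fit))
permutation_fdr_ttest <- function(mat, design, group1, group2,
                                  n_permutations = 250, seed = 1L, s0 = 0,
                                  fdr_threshold = 0.01, fc_threshold = 2) {
  if (is.data.frame(mat)) {
    tib <- mat
    mat <- as.matrix(tib[setdiff(names(tib), "protein_id")])
    rownames(mat) <- tib$protein_id
  }
  if (anyNA(mat)) abort("matrix contains missing values; impute first")
  s1 <- design$sample_id[design$group_id == group1]
  s2 <- design$sample_id[design$group_id == group2]
  idx1 <- match(intersect(s1, colnames(mat)), colnames(mat))
  idx2 <- match(intersect(s2, colnames(mat)), colnames(mat))
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("both groups need >= 2 samples in the matrix")
  }
  n1 <- length(idx1)
  all_idx <- c(idx1, idx2)
  n <- length(all_idx)

  obs <- two_sample_t(mat, idx1, idx2, s0)
  abs_t <- abs(obs$t)

  # null pool: distinct assignments of n1 of the samples to group 1
  combs <- utils::combn(n, n1)
  is_obs <- apply(combs, 2, function(cc) setequal(cc, seq_len(n1)))
  combs <- combs[, !is_obs, drop = FALSE]
  set.seed(as.integer(seed))
  if (ncol(combs) > n_permutations) {
    combs <- combs[, sample(ncol(combs), n_permutations), drop = FALSE]
  }
  n_perm <- ncol(combs)
  if (n_perm == 0) abort("no label permutations available")

  # per permutation, count null |t| >= each observed |t| via sorted lookup
  ord <- order(abs_t, decreasing = TRUE)
  sorted_abs <- abs_t[ord]
  null_counts <- matrix(0, nrow = nrow(mat), ncol = n_perm)
  for (p in seq_len(n_perm)) {
    g1 <- all_idx[combs[, p]]
    g2 <- setdiff(all_idx, g1)
    tp <- abs(two_sample_t(mat, g1, g2, s0)$t)
    # for each sorted threshold, how many null values >= it
    null_counts[, p] <- length(tp) - findInterval(sorted_abs, sort(tp),
                                                 left.open = TRUE)
  }
  med_null <- apply(null_counts, 1, stats::median)
  obs_count <- seq_along(sorted_abs)  # |t| >= threshold among observed
  q_sorted <- pmin(1, pmax(0, med_null / obs_count))
  q_sorted <- cummax(q_sorted)  # monotone nondecreasing as |t| decreases
  q <- numeric(length(abs_t))
  q[ord] <- q_sorted

  p_val <- 2 * stats::pt(-abs_t, df = obs$df)
  res <- tibble::tibble(
    protein_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    difference = obs$difference,
    t_stat = obs$t,
    p_value = p_val,
    neg_log10_p = -log10(pmax(p_val, .Machine$double.xmin)),
    q_value = q,
    passes_selection = q < fdr_threshold & abs(obs$difference) > fc_threshold
  )
  structure(
    list(results = res, group1 = group1, group2 = group2,
         n1 = n1, n2 = length(idx2), n_permutations = n_perm,
         s0 = s0, seed = seed,
         fdr_threshold = fdr_threshold, fc_threshold = fc_threshold),
    class = "perm_fdr_test"
  )
}

#' @export
print.perm_fdr_test <- function(x, ...) {
  cat(sprintf(
    "Permutation-FDR t-test: %s vs %s (n = %d/%d, %d permutations)\n",
    x$group1, x$group2, x$n1, x$n2, x$n_permutations
  ))
  cat(sprintf("  %d / %d proteins pass q < %g & |log2 difference| > %g\n",
              sum(x$results$passes_selection), nrow(x$results),
              x$fdr_threshold, x$fc_threshold))
  invisible(x)
}

#' Select differential candidates by FDR and fold change
#'
#' Two-tailed volcano-style selection: proteins with `q_value` below the
#' FDR threshold and absolute log2 mean difference above the fold-change
#' threshold, in either direction.
#'
#' @param results A `perm_fdr_test` object or its [tidy()] tibble (needs
#'   `protein_id`, `q_value`, `difference`).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param fc_threshold Absolute log2 difference cutoff (default 2).
#' @return Character vector of selected protein ids.
#' @export
select_candidates <- function(results, fdr_threshold = 0.01, fc_threshold = 2) {
  if (inherits(results, "perm_fdr_test")) results <- results$results
  stopifnot(all(c("protein_id", "q_value", "difference") %in% names(results)))
  results$protein_id[results$q_value < fdr_threshold &
                       abs(results$difference) > fc_threshold]
}

#' Z-score hierarchical clustering of selected proteins
#'
#' Each protein row is z-scored across samples (mean 0, SD 1), then rows
#' and columns are clustered agglomeratively with Euclidean distance and
#' average linkage — the standard heatmap ordering for differential
#' protein panels. Constant rows have no defined z-score and are dropped
#' with a warning.
#'
#' @param mat Proteins x samples log2 matrix (no missing values), or tibble
#'   with `protein_id`.
#' @param selected_ids Optional restriction to these protein ids.
#' @return Object of class `zscore_cluster`: list with `z` (z-scored
#'   matrix), `row_order`, `col_order` (labels in dendrogram order),
#'   `row_tree`, `col_tree` (`hclust` objects; `col_tree` is `NULL` for
#'   fewer than 3 samples).
#' @export
zscore_cluster <- function(mat, selected_ids = NULL) {
  if (is.data.frame(mat)) {
    tib <- mat
    mat <- as.matrix(tib[setdiff(names(tib), "protein_id")])
    rownames(mat) <- tib$protein_id
  }
  if (!is.null(selected_ids)) {
    mat <- mat[rownames(mat) %in% selected_ids, , drop = FALSE]
  }
  if (nrow(mat) < 2) abort("need at least 2 rows to cluster")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant row(s); z-score undefined", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(mat) < 2) abort("fewer than 2 non-constant rows remain")
  }
  z <- (mat - rowMeans(mat)) / sds
  row_tree <- stats::hclust(stats::dist(z), method = "average")
  col_tree <- if (ncol(z) >= 3) {
    stats::hclust(stats::dist(t(z)), method = "average")
  } else {
    NULL
  }
  structure(
    list(
      z = z,
      row_order = rownames(z)[row_tree$order],
      col_order = if (is.null(col_tree)) colnames(z) else colnames(z)[col_tree$order],
      row_tree = row_tree,
      col_tree = col_tree
    ),
    class = "zscore_cluster"
  )
}

#' Principal component analysis of samples
#'
#' Centred (unscaled) PCA with samples as observations, reporting scores
#' and the fraction of variance per component. Missing values must be
#' imputed first (the screening chain reuses [impute_downshift()] for
#' this, as for testing).
#'
#' @param mat Proteins x samples log2 matrix (no missing values), or tibble
#'   with `protein_id`.
#' @param design Optional design tibble used to attach group labels to the
#'   scores.
#' @return Object of class `sample_pca`: `scores` tibble (sample_id, group
#'   if available, PC columns) and `variance_explained` (numeric, sums
#'   to 1, nonincreasing).
#' @export
pca_samples <- function(mat, design = NULL) {
  if (is.data.frame(mat)) {
    tib <- mat
    mat <- as.matrix(tib[setdiff(names(tib), "protein_id")])
    rownames(mat) <- tib$protein_id
  }
  if (anyNA(mat)) abort("matrix contains missing values; impute first")
  x <- t(mat)  # samples as rows
  if (nrow(x) < 2) abort("need at least 2 samples")
  if (all(apply(x, 2, stats::var) == 0)) abort("zero-variance data")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), scores)
  if (!is.null(design)) {
    scores <- dplyr::left_join(
      scores, dplyr::select(design, "sample_id", "group_id"), by = "sample_id"
    ) %>%
      dplyr::relocate("group_id", .after = "sample_id")
  }
  structure(list(scores = scores, variance_explained = ve, prcomp = fit),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("Sample PCA: %d samples, PC1+PC2 explain %.2f%% of variance\n",
              nrow(x$scores), 100 * sum(ve[seq_len(min(2, length(ve)))])))
  invisible(x)
}
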