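#' Tidy a permutation-FDR test
#'
#' @param x A `perm_fdr_test` object.
#' @param ... Unused.
#' @return Per-protein tibble: `protein_id`, `difference` (log2,
#'   group2 - group1), `t_stat`, `p_value`, `neg_log10_p`, `q_value`,
#'   `passes_selection`.
#' @method tidy perm_fdr_test
#' @export
tidy.perm_fdr_test <- function(x, ...) {
  x$results
}

#' One-row summary of a permutation-FDR test
#'
#' @param x A `perm_fdr_test` object.
#' @param ... Unused.
#' @return Tibble: groups, sample sizes, permutation count, number of
#'   proteins tested and selected.
#' @method glance perm_fdr_test
#' @export
glance.perm_fdr_test <- function(x, ...) {
  tibble::tibble(
    group1 = x$group1, group2 = x$group2, n1 = x$n1, n2 = x$n2,
    n_permutations = x$n_permutations, s0 = x$s0,
    n_proteins = nrow(x$results),
    n_selected = sum(x$results$passes_selection),
    fdr_threshold = x$fdr_threshold, fc_threshold = x$fc_threshold
  )
}

#' Tidy a Mann-Whitney rank test
#'
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @return One-row tibble mirroring a validation summary table: rank sums,
#'   `U`, `z`, `p_value`, `z_adjusted`, `p_adjusted`, group sizes.
#' @method tidy rank_test
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(
    n1 = x$n1, n2 = x$n2,
    rank_sum1 = x$rank_sum1, rank_sum2 = x$rank_sum2,
    U = x$U, z = x$z, p_value = x$p_value,
    z_adjusted = x$z_adjusted, p_adjusted = x$p_adjusted
  )
}

#' Tidy a sample PCA
#'
#' @param x A `sample_pca` object.
#' @param ... Unused.
#' @return Scores tibble (`sample_id`, optional `group_id`, PC columns).
#' @method tidy sample_pca
#' @export
tidy.sample_pca <- function(x, ...) {
  x$scores
}

#' Variance summary of a sample PCA
#'
#' @param x A `sample_pca` object.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`,
#'   `variance_explained`, `cumulative`.
#' @method glance sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_explained),
    variance_explained = x$variance_explained,
    cumulative = cumsum(x$variance_explained)
  )
}

#' Tidy a random-forest classification result
#'
#' @param x An `aab_forest` object.
#' @param ... Unused.
#' @return Predictions tibble (`sample_id`, `observed`, `predicted`).
#' @method tidy aab_forest
#' @export
tidy.aab_forest <- function(x, ...) {
  x$predictions
}

#' One-row performance summary of a random-forest classifier
#'
#' @param x An `aab_forest` object.
#' @param ... Unused.
#' @return Tibble with confusion counts and exact/rounded rates.
#' @method glance aab_forest
#' @export
glance.aab_forest <- function(x, ...) {
  glance(x$metrics)
}

#' One-row summary of confusion metrics
#'
#' @param x A `confusion_metrics` object.
#' @param ... Unused.
#' @return Tibble: `tp`, `fn`, `tn`, `fp`, exact percent rates and their
#'   rounded integers.
#' @method glance confusion_metrics
#' @export
glance.confusion_metrics <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy,
    sensitivity_rounded = x$sensitivity_rounded,
    specificity_rounded = x$specificity_rounded,
    accuracy_rounded = x$accuracy_rounded
  )
}
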