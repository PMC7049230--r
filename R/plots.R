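#' Volcano plot of a permutation-FDR screen
#'
#' Log2 mean difference against -log10 p-value; proteins passing the
#' FDR + fold-change selection are coloured by direction (lower/higher in
#' group 2).
#'
#' @param object A `perm_fdr_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_fdr_test
#' @export
autoplot.perm_fdr_test <- function(object, ...) {
  d <- object$results %>%
    dplyr::mutate(status = dplyr::case_when(
      .data$passes_selection & .data$difference > 0 ~ "higher",
      .data$passes_selection & .data$difference < 0 ~ "lower",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$difference, .data$neg_log10_p,
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$fc_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(higher = "#c0392b", lower = "#2c6fbb", ns = "grey70")
    ) +
    ggplot2::labs(
      x = sprintf("log2 difference (%s - %s)", object$group2, object$group1),
      y = expression(-log[10] ~ italic(p)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' PCA score plot of samples
#'
#' @param object A `sample_pca` object.
#' @param components Two component indices to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, components = 1:2, ...) {
  ve <- object$variance_explained
  pcs <- paste0("PC", components)
  aes <- if ("group_id" %in% names(object$scores)) {
    ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]], colour = .data$group_id)
  } else {
    ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]])
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * ve[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * ve[components[2]]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Predicted-vs-observed bars for a classifier
#'
#' Test-set counts of predicted labels within each observed class — the
#' visual usually shown next to sensitivity/specificity figures.
#'
#' @param object An `aab_forest` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aab_forest
#' @export
autoplot.aab_forest <- function(object, ...) {
  d <- object$predictions %>%
    dplyr::count(.data$observed, .data$predicted)
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$n, fill = .data$predicted)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "observed class", y = "test samples", fill = "predicted") +
    ggplot2::theme_minimal()
}

#' Relative-abundance bar chart of captured antigens
#'
#' iBAQ molar fractions of a group's antigen repertoire, descending.
#'
#' @param abundance Tibble from [ibaq_fractions()].
#' @param top Show only the `top` most abundant antigens (default 20).
#' @return A ggplot object.
#' @export
plot_ibaq_fractions <- function(abundance, top = 20) {
  d <- utils::head(dplyr::arrange(abundance, dplyr::desc(.data$ibaq_fraction)), top)
  d$protein_id <- factor(d$protein_id, levels = rev(d$protein_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$ibaq_fraction, .data$protein_id)) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::labs(x = "iBAQ fraction of group total (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-target NFI distributions by cohort group
#'
#' Log2 NFI box plots, cases vs controls per target.
#'
#' @param nfi Wide NFI tibble.
#' @param cohort Cohort tibble with `sample_id`, `group`.
#' @return A ggplot object.
#' @export
plot_nfi_distributions <- function(nfi, cohort) {
  long <- tibble::as_tibble(nfi) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "target_id", values_to = "nfi") %>%
    dplyr::left_join(dplyr::select(cohort, "sample_id", "group"), by = "sample_id")
  ggplot2::ggplot(long, ggplot2::aes(.data$target_id, log2(.data$nfi),
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "log2 NFI", fill = NULL) +
    ggplot2::theme_minimal()
}
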