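#' Drop manually flagged spots
#'
#' Removes spots whose quality flag is not `"ok"` (scanner-software or
#' manual poor-quality flags).
#'
#' @param spots Spot-level tibble (see [simulate_array_dataset()] or
#'   [read_spot_table()]).
#' @return The tibble without flagged spots.
#' @export
drop_flagged_spots <- function(spots) {
  if (!"flag" %in% names(spots)) {
    return(spots)
  }
  spots %>% dplyr::filter(.data$flag == "ok")
}

#' Net spot signal after local-background subtraction
#'
#' `net = foreground - local_background`; spots whose net signal is
#' strictly negative are set missing (a spot darker than its surroundings
#' carries no usable signal). A net of exactly zero is kept.
#'
#' @param spots Spot tibble with `foreground` and `local_background`.
#' @return The tibble with a `net` column (`NA` where negative).
#' @export
net_signal <- function(spots) {
  spots %>%
    dplyr::mutate(
      net = .data$foreground - .data$local_background,
      net = ifelse(.data$net < 0, NA_real_, .data$net)
    )
}

#' Subtract the negative-control signal
#'
#' The buffer-blank (negative-control) spots measure unspecific binding of
#' the fluorescent secondary antibody. Their mean net signal is subtracted
#' from every antigen and IgG spot; results that fall below zero become
#' missing. Scope is per subarray by default (each serum occupies one
#' subarray, and unspecific secondary binding is serum-specific) or per
#' slide.
#'
#' @param spots Spot tibble with a `net` column (see [net_signal()]).
#' @param scope `"subarray"` (default) or `"slide"`.
#' @return The tibble with `net` corrected on antigen/IgG spots.
#' @export
subtract_negative_control <- function(spots, scope = c("subarray", "slide")) {
  scope <- match.arg(scope)
  keys <- if (scope == "subarray") c("slide_id", "subarray_id") else "slide_id"
  neg <- spots %>%
    dplyr::filter(.data$spot_role == "negative_control") %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(neg_mean = mean(.data$net, na.rm = TRUE), .groups = "drop")
  units <- spots %>% dplyr::distinct(dplyr::across(dplyr::all_of(keys)))
  uncovered <- dplyr::anti_join(units, neg, by = keys)
  if (nrow(uncovered) > 0) {
    abort(paste0(
      "no negative-control spots in ", scope, ": ",
      paste(do.call(paste, c(uncovered, sep = "/")), collapse = ", ")
    ))
  }
  spots %>%
    dplyr::left_join(neg, by = keys) %>%
    dplyr::mutate(
      net = ifelse(
        .data$spot_role %in% c("antigen", "igg_control"),
        ifelse(.data$net - .data$neg_mean < 0, NA_real_, .data$net - .data$neg_mean),
        .data$net
      )
    ) %>%
    dplyr::select(-"neg_mean")
}

#' Average replicate spots into one intensity per sample and target
#'
#' Mean of the nonmissing replicate spots for each (sample, target); if all
#' replicates are missing, the mean is missing.
#'
#' @param spots Spot tibble with `net` (negative-control-corrected).
#' @return Long tibble with `sample_id`, `slide_id`, `subarray_id`,
#'   `target_id`, `spot_role`, `intensity`, `n_spots`.
#' @export
average_replicates <- function(spots) {
  spots %>%
    dplyr::group_by(.data$sample_id, .data$slide_id, .data$subarray_id,
                    .data$target_id, .data$spot_role) %>%
    dplyr::summarise(
      intensity = if (all(is.na(.data$net))) NA_real_ else mean(.data$net, na.rm = TRUE),
      n_spots = dplyr::n(),
      .groups = "drop"
    )
}

#' IgG median-centring normalization
#'
#' Each subarray's IgG positive-control median is divided by the overall
#' IgG median — the median of the per-subarray medians — to yield that
#' subarray's normalization factor; every intensity on the subarray is
#' then divided by the factor. After centring, all subarrays share the
#' same IgG median, which removes per-well batch effects (incubation,
#' scanning) that act multiplicatively. Taking the median of medians as
#' the overall reference makes the factor of one subarray independent of
#' how many control spots another subarray contributes, and rescaling a
#' non-median subarray leaves every other subarray's factor unchanged.
#'
#' @param means Long tibble from [average_replicates()].
#' @return Object of class `nfi_matrix`: a wide tibble (`sample_id` +
#'   one column per antigen target) of normalized fluorescence
#'   intensities, with attributes `norm_factors` (tibble sample_id,
#'   igg_median, factor) and `audit` (stage log, extended by later
#'   stages).
#' @export
igg_median_centring <- function(means) {
  igg <- means %>%
    dplyr::filter(.data$spot_role == "igg_control", !is.na(.data$intensity))
  if (nrow(igg) == 0) abort("no observed IgG control values")
  per_sub <- igg %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(igg_median = stats::median(.data$intensity), .groups = "drop")
  no_igg <- setdiff(unique(means$sample_id), per_sub$sample_id)
  if (length(no_igg) > 0) {
    abort(paste0("subarray(s) without observed IgG values: ",
                 paste(no_igg, collapse = ", ")))
  }
  if (any(per_sub$igg_median <= 0)) {
    abort("nonpositive IgG median; cannot form normalization factor")
  }
  global_med <- stats::median(per_sub$igg_median)
  per_sub$factor <- per_sub$igg_median / global_med

  wide <- means %>%
    dplyr::filter(.data$spot_role == "antigen") %>%
    dplyr::left_join(dplyr::select(per_sub, "sample_id", "factor"), by = "sample_id") %>%
    dplyr::mutate(nfi = .data$intensity / .data$factor) %>%
    dplyr::select("sample_id", "target_id", "nfi") %>%
    tidyr::pivot_wider(names_from = "target_id", values_from = "nfi") %>%
    dplyr::arrange(.data$sample_id)

  new_nfi_matrix(wide, norm_factors = per_sub,
                 audit = tibble::tibble(
                   stage = "igg_median_centring",
                   n_targets = ncol(wide) - 1L,
                   n_missing = sum(is.na(wide[-1]))
                 ))
}

#' @keywords internal
#' @noRd
new_nfi_matrix <- function(wide, norm_factors = NULL, audit = NULL) {
  out <- tibble::as_tibble(wide)
  attr(out, "norm_factors") <- norm_factors
  attr(out, "audit") <- audit
  class(out) <- c("nfi_matrix", class(tibble::tibble()))
  out
}

#' @keywords internal
#' @noRd
append_audit <- function(nfi, stage) {
  audit <- attr(nfi, "audit")
  entry <- tibble::tibble(
    stage = stage,
    n_targets = ncol(nfi) - 1L,
    n_missing = sum(is.na(nfi[-1]))
  )
  attr(nfi, "audit") <- dplyr::bind_rows(audit, entry)
  nfi
}

#' Winsorize extreme values to missing
#'
#' Per target (across samples), observed values strictly below the lower
#' or strictly above the upper percentile are set missing rather than
#' clamped, so outliers neither enter the statistics nor masquerade as
#' real boundary values. Percentiles use linear-interpolation quantiles.
#'
#' @param nfi Wide NFI tibble (`sample_id` + target columns).
#' @param lower_pct,upper_pct Percentile bounds (defaults 5 and 95).
#' @return The NFI tibble with tail values set to `NA`.
#' @export
winsorize_to_missing <- function(nfi, lower_pct = 5, upper_pct = 95) {
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  targets <- setdiff(names(nfi), "sample_id")
  for (t in targets) {
    x <- nfi[[t]]
    obs <- x[!is.na(x)]
    if (length(obs) == 0) next
    qs <- stats::quantile(obs, c(lower_pct, upper_pct) / 100,
                          names = FALSE, type = 7)
    x[!is.na(x) & (x < qs[1] | x > qs[2])] <- NA_real_
    nfi[[t]] <- x
  }
  append_audit(nfi, "winsorize_to_missing")
}

#' Drop targets with excessive missingness
#'
#' Target columns whose overall missing fraction is strictly greater than
#' `max_missing` are removed from the analysis set; the remainder proceed
#' to imputation.
#'
#' @param nfi Wide NFI tibble.
#' @param max_missing Maximum tolerated missing fraction (default 0.25).
#' @return The NFI tibble without over-missing targets.
#' @export
missingness_filter <- function(nfi, max_missing = 0.25) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  targets <- setdiff(names(nfi), "sample_id")
  frac <- vapply(targets, function(t) mean(is.na(nfi[[t]])), numeric(1))
  drop <- targets[frac > max_missing]
  out <- nfi[, !(names(nfi) %in% drop), drop = FALSE]
  attr(out, "norm_factors") <- attr(nfi, "norm_factors")
  attr(out, "audit") <- attr(nfi, "audit")
  class(out) <- class(nfi)
  append_audit(out, "missingness_filter")
}

#' K-nearest-neighbour imputation over target columns
#'
#' For each missing cell, the k most similar target columns (Euclidean
#' distance over co-observed samples, scaled to per-coordinate RMS so
#' columns with different overlap are comparable) supply the value: the
#' unweighted mean over neighbours of the neighbour's value in that row,
#' adjusted by the difference of the two columns' means over their
#' co-observed samples. The adjustment makes imputation exact for
#' duplicate or parallel-shifted columns. Observed cells are never
#' altered.
#'
#' @param nfi Wide NFI tibble after [missingness_filter()].
#' @param k Number of neighbour columns (default 10); fewer are used when
#'   fewer have co-observations. A sample row with no observed value in
#'   any neighbour column (possible when a dim sample falls below every
#'   target's lower winsorization bound) falls back to the target's
#'   column mean; a target with no co-observed neighbour column at all is
#'   an error.
#' @return The NFI tibble with no missing cells.
#' @export
knn_impute <- function(nfi, k = 10) {
  stopifnot(k >= 1)
  targets <- setdiff(names(nfi), "sample_id")
  m <- as.matrix(nfi[targets])
  if (!anyNA(m)) {
    return(append_audit(nfi, "knn_impute"))
  }
  p <- ncol(m)
  # pairwise RMS distance and column means over co-observed rows
  d <- matrix(Inf, p, p)
  mean_self <- matrix(NA_real_, p, p)   # mean of column i over co-obs with j
  mean_other <- matrix(NA_real_, p, p)  # mean of column j over co-obs with i
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      co <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(co) >= 2) {
        d[i, j] <- sqrt(mean((m[co, i] - m[co, j])^2))
        mean_self[i, j] <- mean(m[co, i])
        mean_other[i, j] <- mean(m[co, j])
      }
    }
  }
  out <- m
  col_means <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(p)) {
    miss_rows <- which(is.na(m[, j]))
    if (length(miss_rows) == 0) next
    if (!any(is.finite(d[j, ]))) {
      abort(sprintf("no neighbour with co-observations for target %s",
                    targets[j]))
    }
    ord <- order(d[j, ])
    for (r in miss_rows) {
      cand <- ord[is.finite(d[j, ord]) & !is.na(m[r, ord])]
      if (length(cand) == 0) {
        # fully missing row: no neighbour carries a value for this sample
        out[r, j] <- col_means[j]
        next
      }
      nb <- cand[seq_len(min(k, length(cand)))]
      out[r, j] <- mean(m[r, nb] + mean_self[j, nb] - mean_other[j, nb])
    }
  }
  for (t in targets) nfi[[t]] <- out[, t]
  append_audit(nfi, "knn_impute")
}

#' Full microarray pre-processing pipeline
#'
#' Composition, in order: flagged-spot removal, local-background
#' subtraction, negative-control subtraction, replicate averaging, IgG
#' median-centring, winsorize-to-missing, missingness filtering, KNN
#' imputation. The per-stage audit (targets retained, missing cells) is
#' attached to the result and retrievable with [preprocess_audit()].
#'
#' @param spots Spot-level tibble.
#' @param lower_pct,upper_pct Winsorization percentiles.
#' @param max_missing Target missingness cutoff.
#' @param k KNN neighbour count.
#' @param negctrl_scope `"subarray"` or `"slide"` negative-control scope.
#' @return An `nfi_matrix` tibble with no missing values.
#' @export
#' @examples
#' cfg <- array_sim_config(n_slides = 1, subarrays_per_slide = 4,
#'                         cohort_sizes = c(2, 2), seed = 9)
#' sim <- simulate_array_dataset(cfg)
#' nfi <- preprocess_array(sim$spots)
#' dim(nfi)
preprocess_array <- function(spots, lower_pct = 5, upper_pct = 95,
                             max_missing = 0.25, k = 10,
                             negctrl_scope = c("subarray", "slide")) {
  negctrl_scope <- match.arg(negctrl_scope)
  spots %>%
    drop_flagged_spots() %>%
    net_signal() %>%
    subtract_negative_control(scope = negctrl_scope) %>%
    average_replicates() %>%
    igg_median_centring() %>%
    winsorize_to_missing(lower_pct, upper_pct) %>%
    missingness_filter(max_missing) %>%
    knn_impute(k)
}

#' Per-stage audit log of a pre-processed NFI matrix
#'
#' @param nfi An `nfi_matrix` from [preprocess_array()].
#' @return Tibble with one row per pipeline stage (targets retained,
#'   missing-cell count after the stage).
#' @export
preprocess_audit <- function(nfi) {
  attr(nfi, "audit")
}

#' Per-subarray normalization factors of an NFI matrix
#'
#' @param nfi An `nfi_matrix`.
#' @return Tibble with `sample_id`, `igg_median`, `factor`.
#' @export
norm_factors <- function(nfi) {
  attr(nfi, "norm_factors")
}
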