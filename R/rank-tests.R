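#' Mann-Whitney U test with tie-adjusted Z
#'
#' Rank-based two-sample test using midranks on the pooled data. Reports
#' both rank sums, `U = min(U1, U2)` (the convention of classical
#' statistics packages), the normal-approximation `Z` computed from the
#' first group's U (`z = (U1 - n1 n2 / 2) / sqrt(n1 n2 (N + 1) / 12)`, no
#' continuity correction), and the tie-corrected `z_adjusted` using the
#' variance `n1 n2 / 12 * [(N + 1) - sum(t^3 - t) / (N (N - 1))]` over tie
#' groups of size `t`. Two-sided p-values from the normal approximation.
#'
#' @param x,y Numeric sample vectors (group 1 and group 2), `NA` dropped.
#' @param group_names Length-2 character for labelling (default
#'   `c("group1", "group2")`).
#' @return Object of class `rank_test` (see [tidy.rank_test()]): rank sums,
#'   `U1`, `U2`, `U`, `z`, `p_value`, `z_adjusted`, `p_adjusted`, `n1`,
#'   `n2`.
#' @export
#' @examples
#' mann_whitney(rnorm(20, 1), rnorm(20))
mann_whitney <- function(x, y, group_names = c("group1", "group2")) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("both samples need n >= 2")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    abort("all values identical across both groups; rank variance is zero")
  }
  r <- rank(pooled)  # midranks
  rank_sum1 <- sum(r[seq_len(n1)])
  rank_sum2 <- sum(r[n1 + seq_len(n2)])
  u1 <- rank_sum1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  n <- n1 + n2

  sigma2 <- n1 * n2 * (n + 1) / 12
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)

  tie_sizes <- as.integer(table(pooled))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2_adj <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2_adj <= 0) abort("tie-corrected variance is zero")
  z_adj <- (u1 - n1 * n2 / 2) / sqrt(sigma2_adj)

  structure(
    list(
      group_names = group_names,
      n1 = n1, n2 = n2,
      rank_sum1 = rank_sum1, rank_sum2 = rank_sum2,
      U1 = u1, U2 = u2, U = min(u1, u2),
      z = z, p_value = 2 * stats::pnorm(-abs(z)),
      z_adjusted = z_adj, p_adjusted = 2 * stats::pnorm(-abs(z_adj))
    ),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test (%s vs %s): U = %g, Z = %.3f (adj. %.3f), p = %.4g\n",
    x$group_names[1], x$group_names[2], x$U, x$z, x$z_adjusted, x$p_adjusted
  ))
  invisible(x)
}

#' U and Z statistics from printed rank sums
#'
#' Reconstructs the Mann-Whitney statistics when only the first group's
#' rank sum and the group sizes are available (as in published summary
#' tables): `U1 = rank_sum1 - n1(n1+1)/2`, `U = min(U1, n1 n2 - U1)`, `z`
#' from the untied normal approximation, and `z_adjusted` only when a tie
#' spectrum (vector of tie-group sizes) is supplied.
#'
#' @param rank_sum1 Rank sum of group 1 (midranks).
#' @param n1,n2 Group sizes.
#' @param tie_spectrum Optional integer vector of tie-group sizes.
#' @return One-row tibble with `U1`, `U`, `z`, `p_value`, and
#'   `z_adjusted`/`p_adjusted` when a tie spectrum is given.
#' @export
#' @examples
#' u_z_from_rank_sums(16741, 120, 120)  # U = 4919, z = 4.242
u_z_from_rank_sums <- function(rank_sum1, n1, n2, tie_spectrum = NULL) {
  lo <- n1 * (n1 + 1) / 2
  hi <- n1 * n2 + lo
  if (rank_sum1 < lo || rank_sum1 > hi) {
    abort(sprintf("rank sum %g out of range [%g, %g] for n1 = %d, n2 = %d",
                  rank_sum1, lo, hi, n1, n2))
  }
  u1 <- rank_sum1 - lo
  u <- min(u1, n1 * n2 - u1)
  n <- n1 + n2
  z <- (u1 - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  out <- tibble::tibble(
    U1 = u1, U = u, z = z, p_value = 2 * stats::pnorm(-abs(z))
  )
  if (!is.null(tie_spectrum)) {
    tie_term <- sum(tie_spectrum^3 - tie_spectrum)
    sigma2_adj <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z_adj <- (u1 - n1 * n2 / 2) / sqrt(sigma2_adj)
    out$z_adjusted <- z_adj
    out$p_adjusted <- 2 * stats::pnorm(-abs(z_adj))
  }
  out
}

#' Spearman rank correlation with t-statistic
#'
#' Pairwise-complete Spearman rho (Pearson correlation of midranks) with
#' the t approximation `t = R sqrt((N - 2) / (1 - R^2))` on `N - 2`
#' degrees of freedom — the summary convention of clinical correlation
#' tables (valid N varies per variable pair).
#'
#' @param x,y Numeric vectors; pairs with any missing value are dropped.
#' @return One-row tibble: `valid_n`, `rho`, `t`, `p_value`. Perfect
#'   correlation yields `t = +/-Inf` and `p_value = 0`.
#' @export
#' @examples
#' spearman_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("constant input; correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1 - 1e-12) {
    rho <- sign(rho)
  }
  if (abs(rho) >= 1) {
    t <- sign(rho) * Inf
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  tibble::tibble(valid_n = n, rho = rho, t = t, p_value = p)
}

#' Kruskal-Wallis rank ANOVA for three or more groups
#'
#' Tie-corrected H statistic with a chi-square reference on `g - 1`
#' degrees of freedom (delegates to [stats::kruskal.test()]). For two
#' groups use [mann_whitney()].
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return One-row tibble: `H`, `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.factor(as.character(groups[ok]))
  g <- nlevels(groups)
  if (g < 3) abort("need at least 3 groups; use mann_whitney() for 2")
  if (any(table(groups) < 2)) abort("every group needs n >= 2")
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n_groups = g
  )
}

#' Shapiro-Wilk normality pre-check
#'
#' Routes the analysis: when normality is rejected the nonparametric track
#' (Mann-Whitney, Spearman, Kruskal-Wallis) is used. Valid for
#' 3 <= n <= 5000.
#'
#' @param values Numeric vector; `NA` dropped.
#' @return One-row tibble: `W`, `p_value`, `n`, `normal` (at alpha 0.05).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n))
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(
    W = unname(sw$statistic), p_value = sw$p.value, n = n,
    normal = sw$p.value >= 0.05
  )
}

#' Case/control rank tests for every target of an NFI matrix
#'
#' Runs [mann_whitney()] per target column, cases vs controls — the shape
#' of a microarray validation summary table (rank sums, U, Z, p, adjusted
#' Z, adjusted p per autoantibody).
#'
#' @param nfi Wide NFI tibble (`sample_id` + target columns).
#' @param cohort Cohort tibble with `sample_id` and `group`.
#' @param case,control Group labels (defaults `"POAG"`, `"CTRL"`).
#' @return Tibble with one row per target.
#' @export
validate_targets <- function(nfi, cohort, case = "POAG", control = "CTRL") {
  targets <- setdiff(names(nfi), "sample_id")
  joined <- dplyr::left_join(nfi, dplyr::select(cohort, "sample_id", "group"),
                             by = "sample_id")
  purrr::map_dfr(targets, function(t) {
    res <- mann_whitney(
      joined[[t]][joined$group == case],
      joined[[t]][joined$group == control],
      group_names = c(case, control)
    )
    dplyr::bind_cols(tibble::tibble(target_id = t), tidy(res))
  })
}

#' Rank correlations of autoantibody levels with clinical parameters
#'
#' [spearman_test()] of each target column against each clinical
#' covariate, restricted to cases by default (clinical staging is only
#' defined for patients); pairwise-complete, so valid N varies. Pairs
#' with fewer than 3 complete observations (or a constant variable)
#' yield an `NA` row rather than an error.
#'
#' @param nfi Wide NFI tibble.
#' @param cohort Cohort tibble with `sample_id`, `group` and the clinical
#'   columns.
#' @param parameters Clinical column names (default `c("cdr", "md", "iop")`).
#' @param group Restrict to this cohort group (default `"POAG"`); `NULL`
#'   uses everyone.
#' @return Tibble: `parameter`, `target_id`, `valid_n`, `rho`, `t`,
#'   `p_value`.
#' @export
correlate_clinical <- function(nfi, cohort, parameters = c("cdr", "md", "iop"),
                               group = "POAG") {
  targets <- setdiff(names(nfi), "sample_id")
  joined <- dplyr::left_join(nfi, cohort, by = "sample_id")
  if (!is.null(group)) joined <- joined[joined$group %in% group, , drop = FALSE]
  grid <- tidyr::expand_grid(parameter = parameters, target_id = targets)
  purrr::pmap_dfr(grid, function(parameter, target_id) {
    res <- tryCatch(
      spearman_test(joined[[target_id]], joined[[parameter]]),
      error = function(e) tibble::tibble(
        valid_n = sum(stats::complete.cases(joined[[target_id]],
                                            joined[[parameter]])),
        rho = NA_real_, t = NA_real_, p_value = NA_real_
      )
    )
    dplyr::bind_cols(tibble::tibble(parameter = parameter,
                                    target_id = target_id), res)
  })
}
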