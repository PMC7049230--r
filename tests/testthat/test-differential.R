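test_that("down-shift imputation follows the stated normal law", {
  # no missing cells -> identity
  m <- matrix(rnorm(40, 25), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_identical(impute_downshift(m, seed = 1), m)

  # column with < 2 observed values -> error
  bad <- m
  bad[, 2] <- NA
  expect_error(impute_downshift(bad, seed = 1), "fewer than 2 observed")

  # Monte-Carlo: imputed values match N(mean - 1.8 sd, (0.3 sd)^2)
  set.seed(10)
  obs <- rnorm(200, mean = 25, sd = 2)
  col <- c(obs, rep(NA_real_, 1e4))
  big <- matrix(col, ncol = 1, dimnames = list(NULL, "s1"))
  out <- impute_downshift(big, seed = 3)
  imputed <- out[201:length(col), 1]
  mu_target <- mean(obs) - 1.8 * sd(obs)
  se <- 0.3 * sd(obs) / sqrt(1e4)
  expect_lt(abs(mean(imputed) - mu_target), 3 * se)
  expect_equal(sd(imputed), 0.3 * sd(obs), tolerance = 0.05)
  # observed cells untouched
  expect_identical(out[1:200, 1], obs)
})

test_that("permutation-FDR test is reproducible and order-invariant", {
  design <- tiny_design()
  sim <- simulate_ms_dataset(ms_sim_config(
    n_proteins = 50, n_background_shared = 0, n_differential = 5,
    censor_quantile = 0, seed = 21
  ))
  samples <- sim$design$sample_id[sim$design$group_id %in% c("CH", "CG")]
  mat <- log2_intensity_matrix(sim$quant, sim$design, samples)
  f1 <- permutation_fdr_ttest(mat, sim$design, "CH", "CG", seed = 4)
  f2 <- permutation_fdr_ttest(mat, sim$design, "CH", "CG", seed = 4)
  expect_identical(tidy(f1), tidy(f2))

  perm <- sample(nrow(mat))
  f3 <- permutation_fdr_ttest(mat[perm, ], sim$design, "CH", "CG", seed = 4)
  r1 <- tidy(f1)[order(tidy(f1)$protein_id), ]
  r3 <- tidy(f3)[order(tidy(f3)$protein_id), ]
  expect_equal(r1$q_value, r3$q_value)
  expect_equal(r1$t_stat, r3$t_stat)
})

test_that("exchangeable two-protein toy yields q = 1", {
  design <- tiny_design()
  # symmetric under label swap: group means identical
  mat <- rbind(
    p1 = c(1, 2, 3, 1, 2, 3),
    p2 = c(5, 6, 7, 5, 6, 7)
  )
  colnames(mat) <- design$sample_id[design$group_id %in% c("A", "B")]
  fit <- permutation_fdr_ttest(mat, design, "A", "B", seed = 1)
  expect_true(all(tidy(fit)$q_value == 1))
})

test_that("large true shifts are recovered at q < 0.01 and |difference| > 2", {
  # Replicate noise 0.3 keeps the weakest true |t| clear of the pooled
  # permutation null's fat tail; at 3-vs-3 the q resolution is limited by
  # chance alignments of null noise with a label split, so borderline |t|
  # values cannot reach q < 0.01 regardless of the true effect.
  recovered <- vapply(1:5, function(s) {
    sim <- simulate_ms_dataset(ms_sim_config(
      n_proteins = 200, n_background_shared = 0, n_differential = 20,
      effect_log2 = 4, noise_sd_log2 = 0.3, censor_quantile = 0, seed = s
    ))
    samples <- sim$design$sample_id[sim$design$group_id %in% c("CH", "CG")]
    mat <- log2_intensity_matrix(sim$quant, sim$design, samples)
    fit <- permutation_fdr_ttest(mat, sim$design, "CH", "CG", seed = s)
    hits <- select_candidates(fit, 0.01, 2)
    sum(sim$truth$differential_protein_ids %in% hits) >= 18
  }, logical(1))
  expect_true(mean(recovered) >= 0.9)
})

test_that("candidate selection applies both thresholds, two-tailed and monotone", {
  tab <- reference_table("candidate_volcano")
  res <- tibble::tibble(
    protein_id = tab$gene,
    difference = tab$difference,
    q_value = 0  # all printed rows passed the screen's FDR criterion
  )
  sel <- select_candidates(res, fdr_threshold = 0.01, fc_threshold = 2)
  expect_identical(length(sel), 18L)
  failed <- setdiff(res$protein_id, sel)
  expect_setequal(round(abs(res$difference[match(failed, res$protein_id)]), 3),
                  c(1.816, 1.819, 1.950))
  # both tails selected
  expect_true(any(res$difference[match(sel, res$protein_id)] < 0))

  # monotone in both thresholds
  expect_true(all(select_candidates(res, 0.01, 3) %in% sel))
  expect_identical(select_candidates(tibble::tibble(
    protein_id = "x", difference = 5, q_value = 1
  )), character(0))
  expect_identical(
    select_candidates(res[0, ]), character(0)
  )
})

test_that("z-score clustering recovers planted blocks and standardizes rows", {
  set.seed(31)
  n_up <- 27
  n_down <- 11
  base <- matrix(rnorm(6 * (n_up + n_down), 0, 0.3), ncol = 6)
  base[1:n_down, 4:6] <- base[1:n_down, 4:6] - 3
  base[(n_down + 1):(n_down + n_up), 4:6] <-
    base[(n_down + 1):(n_down + n_up), 4:6] + 3
  rownames(base) <- paste0("P", seq_len(nrow(base)))
  colnames(base) <- paste0("s", 1:6)
  cl <- zscore_cluster(base)
  expect_equal(unname(rowMeans(cl$z)), rep(0, nrow(base)), tolerance = 1e-12)
  expect_equal(unname(apply(cl$z, 1, sd)), rep(1, nrow(base)), tolerance = 1e-12)
  blocks <- stats::cutree(cl$row_tree, k = 2)
  expect_identical(length(unique(blocks[1:n_down])), 1L)
  expect_identical(length(unique(blocks[(n_down + 1):(n_down + n_up)])), 1L)
  expect_false(blocks[1] == blocks[n_down + 1])

  # identical rows merge at height zero
  two <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  cl2 <- zscore_cluster(two)
  expect_equal(min(cl2$row_tree$height), 0)

  # constant rows are dropped with a warning
  with_const <- rbind(base[1:3, ], flat = rep(5, 6))
  expect_warning(cl3 <- zscore_cluster(with_const), "constant")
  expect_identical(nrow(cl3$z), 3L)
})

test_that("sample PCA matches the covariance eigendecomposition", {
  set.seed(17)
  mat <- matrix(rnorm(24, 20), nrow = 4,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  fit <- pca_samples(mat)
  ve <- fit$variance_explained
  expect_equal(sum(ve), 1, tolerance = 1e-12)
  expect_true(all(diff(ve) <= 1e-12))

  # oracle: eigenvalues of the sample covariance of the samples-by-features data
  ev <- eigen(stats::cov(t(mat)), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(ve[seq_along(ev)], ev / sum(ev), tolerance = 1e-9)

  # rank-1 structure dominates PC1
  r1 <- outer(rnorm(5), rnorm(8)) * 10
  r1 <- r1 + matrix(rnorm(40, 0, 1e-3), 5, 8)
  dimnames(r1) <- list(paste0("p", 1:5), paste0("s", 1:8))
  expect_gt(pca_samples(r1)$variance_explained[1], 0.99)

  expect_error(pca_samples(matrix(1, 3, 4,
    dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))), "zero-variance")
})
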