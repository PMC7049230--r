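test_that("Mann-Whitney U equals brute-force pair counting, with and without ties", {
  set.seed(40)
  for (i in 1:20) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    x <- sample(1:10, n1, replace = TRUE)  # ties guaranteed
    y <- sample(1:10, n2, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    res <- mann_whitney(x, y)
    expect_equal(res$U, brute_u(x, y))
    expect_equal(res$U1 + res$U2, n1 * n2)
    expect_equal(res$rank_sum1 + res$rank_sum2,
                 (n1 + n2) * (n1 + n2 + 1) / 2)
    expect_lte(res$U, n1 * n2 / 2)
    expect_gte(abs(res$z_adjusted), abs(res$z))
    # cross-check against the standard implementation (W = U of sample 1)
    w <- suppressWarnings(stats::wilcox.test(x, y))
    expect_equal(res$U1, unname(w$statistic))
  }
})

test_that("Mann-Whitney is invariant under monotone transforms and symmetric on equal sets", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(0.8, 2.9, 6.1, 3.3, 1.9)
  a <- tidy(mann_whitney(x, y))
  b <- tidy(mann_whitney(exp(x), exp(y)))
  expect_equal(a, b)

  # perfectly interleaved samples: U at its maximum n^2/2, z = 0
  interleaved <- mann_whitney(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(interleaved$U, 8)
  expect_equal(interleaved$z, 0)

  expect_error(mann_whitney(rep(2, 5), rep(2, 4)), "identical")
  expect_error(mann_whitney(1, c(2, 3)), "n >= 2")
})

test_that("rank-sum reconstruction reproduces the full test and validates its input", {
  set.seed(41)
  x <- rnorm(15)
  y <- rnorm(12, 0.8)
  res <- mann_whitney(x, y)
  tie_spec <- as.integer(table(c(x, y)))
  back <- u_z_from_rank_sums(res$rank_sum1, 15, 12, tie_spectrum = tie_spec)
  expect_equal(back$U, res$U)
  expect_equal(back$z, res$z)
  expect_equal(back$z_adjusted, res$z_adjusted)

  # extreme rank sum: group 1 holds the lowest ranks
  expect_equal(u_z_from_rank_sums(10 * 11 / 2, 10, 10)$U, 0)
  expect_error(u_z_from_rank_sums(5, 10, 10), "out of range")
})

test_that("Spearman correlation matches the rank-Pearson oracle and t convention", {
  set.seed(42)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  res <- spearman_test(x, y)
  rho_oracle <- stats::cor(rank(x), rank(y))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(res$t, res$rho * sqrt((30 - 2) / (1 - res$rho^2)))
  ct <- stats::cor.test(x, y, method = "spearman")
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)

  # rank invariance: spearman(x, y) = spearman(rank(x), rank(y))
  expect_equal(res$rho, spearman_test(rank(x), rank(y))$rho)

  # missing pairs are dropped (valid N)
  xm <- c(x, NA, 5)
  ym <- c(y, 3, NA)
  expect_identical(spearman_test(xm, ym)$valid_n, 30L)

  mono <- spearman_test(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_identical(mono$t, Inf)
  expect_identical(mono$p_value, 0)

  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:1), "3 complete pairs")
})

test_that("Kruskal-Wallis matches a hand-ranked oracle and holds its type-I error", {
  g1 <- c(2.1, 3.5, 1.2, 4.4)
  g2 <- c(5.1, 6.0, 4.9)
  g3 <- c(0.4, 0.9, 1.8, 2.6)
  values <- c(g1, g2, g3)
  groups <- rep(c("a", "b", "c"), c(4, 3, 4))
  res <- kruskal_wallis(values, groups)
  # hand formula (no ties here): H = 12/(N(N+1)) sum R_g^2/n_g - 3(N+1)
  r <- rank(values)
  rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  n <- length(values)
  h_oracle <- 12 / (n * (n + 1)) * sum(rg^2 / ng) - 3 * (n + 1)
  expect_equal(res$H, h_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)

  # identical group compositions -> H = 0
  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0)

  expect_error(kruskal_wallis(1:4, rep(c("a", "b"), 2)), "3 groups")

  # null rejection rate stays near nominal
  set.seed(43)
  rej <- mean(replicate(1000, {
    kruskal_wallis(rnorm(15), rep(c("a", "b", "c"), each = 5))$p_value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("normality pre-check rejects the simulator's heavy-tailed signals", {
  rejects <- vapply(1:10, function(s) {
    cfg <- array_sim_config(n_slides = 2, subarrays_per_slide = 16,
                            cohort_sizes = c(16, 16), n_targets = 3,
                            differential_targets = numeric(0), seed = s)
    sim <- simulate_array_dataset(cfg)
    ag <- sim$spots[sim$spots$spot_role == "antigen" &
                      sim$spots$target_id == "T01", ]
    net <- ag$foreground - ag$local_background
    normality_check(net)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.9)

  # Gaussian data are rejected only at roughly the nominal rate
  set.seed(44)
  rej <- mean(replicate(200, normality_check(rnorm(100))$p_value < 0.05))
  expect_lt(rej, 0.12)

  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("per-target validation and clinical correlation tables have the expected shape", {
  cfg <- array_sim_config(n_slides = 2, subarrays_per_slide = 16,
                          cohort_sizes = c(16, 16), n_targets = 4,
                          differential_targets = c(T01 = 2), seed = 77)
  sim <- simulate_array_dataset(cfg)
  nfi <- preprocess_array(sim$spots)
  val <- validate_targets(nfi, sim$cohort)
  expect_setequal(val$target_id, setdiff(names(nfi), "sample_id"))
  expect_true(all(val$rank_sum1 + val$rank_sum2 == 32 * 33 / 2))
  expect_true(all(val$U <= 16 * 16 / 2))

  cors <- correlate_clinical(nfi, sim$cohort, parameters = c("cdr", "iop"))
  expect_identical(nrow(cors), 2L * length(val$target_id))
  expect_true(all(cors$valid_n <= 16))
})
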