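test_that("net signal subtracts local background, with negatives becoming missing", {
  spots <- make_spots(data.frame(
    foreground = c(1000, 200, 300),
    local_background = c(300, 300, 300)
  ))
  out <- net_signal(spots)
  expect_equal(out$net, c(700, NA, 0))  # zero net is kept, only < 0 is missing
})

test_that("negative-control subtraction corrects antigen and IgG spots per subarray", {
  spots <- make_spots(data.frame(
    spot_role = c("antigen", "antigen", "igg_control",
                  "negative_control", "negative_control"),
    target_id = c("T01", "T02", "IgG_1", "NEG_1", "NEG_2"),
    foreground = c(700, 30, 900, 40, 60),
    local_background = 0
  ))
  out <- subtract_negative_control(net_signal(spots))
  expect_equal(out$net[out$target_id == "T01"], 650)
  expect_true(is.na(out$net[out$target_id == "T02"]))  # 30 - 50 < 0
  expect_equal(out$net[out$target_id == "IgG_1"], 850)
  # negative-control rows themselves are untouched
  expect_equal(out$net[out$spot_role == "negative_control"], c(40, 60))

  # zero-mean control leaves antigens unchanged
  zero_ctrl <- make_spots(data.frame(
    spot_role = c("antigen", "negative_control"),
    target_id = c("T01", "NEG_1"),
    foreground = c(500, 0), local_background = 0
  ))
  out2 <- subtract_negative_control(net_signal(zero_ctrl))
  expect_equal(out2$net[out2$spot_role == "antigen"], 500)

  # a subarray without negative controls is an error naming the unit
  no_ctrl <- make_spots(data.frame(
    subarray_id = c(1L, 1L, 2L),
    sample_id = c("X1", "X1", "X2"),
    spot_role = c("antigen", "negative_control", "antigen"),
    foreground = 100, local_background = 0
  ))
  expect_error(subtract_negative_control(net_signal(no_ctrl)), "S01/2")
})

test_that("replicate averaging is missing-aware", {
  spots <- make_spots(data.frame(
    target_id = rep(c("T01", "T02", "T03"), each = 3),
    replicate_index = rep(1:3, 3),
    foreground = c(600, 650, 700, 600, 100, 700, 100, 150, 120),
    local_background = c(rep(0, 4), 300, 0, 300, 300, 300)
  ))
  out <- average_replicates(net_signal(spots))
  expect_equal(out$intensity[out$target_id == "T01"], 650)
  expect_equal(out$intensity[out$target_id == "T02"], 650)  # middle replicate missing
  expect_true(is.na(out$intensity[out$target_id == "T03"]))  # all below background
})

test_that("IgG median-centring equalizes per-subarray IgG medians exactly", {
  mk_sub <- function(sample, sub, igg, t1) {
    make_spots(data.frame(
      sample_id = sample, subarray_id = sub,
      target_id = c("T01", "IgG_1", "IgG_2", "IgG_3", "NEG_1"),
      spot_role = c("antigen", "igg_control", "igg_control", "igg_control",
                    "negative_control"),
      foreground = c(t1, igg - 10, igg, igg + 10, 0),
      local_background = 0
    ))
  }
  spots <- rbind(
    mk_sub("X1", 1L, igg = 1000, t1 = 400),
    mk_sub("X2", 2L, igg = 2000, t1 = 800),
    mk_sub("X3", 3L, igg = 1000, t1 = 400)
  )
  means <- average_replicates(subtract_negative_control(net_signal(spots)))
  nfi <- igg_median_centring(means)
  nf <- norm_factors(nfi)
  # global IgG median is 1000; the doubled subarray gets factor 2, halved back
  expect_equal(nf$factor[nf$sample_id == "X2"], 2)
  expect_equal(nf$factor[nf$sample_id == "X1"], 1)
  expect_equal(nfi$T01, c(400, 400, 400))
  # direct recomputation oracle: centred IgG medians all equal
  centred_igg <- nf$igg_median / nf$factor
  expect_equal(centred_igg, rep(centred_igg[1], 3))

  # nonpositive IgG median is an error
  bad_means <- tibble::tibble(
    sample_id = c("X1", "X1", "X2", "X2"),
    slide_id = "S01", subarray_id = c(1L, 1L, 2L, 2L),
    target_id = c("T01", "IgG_1", "T01", "IgG_1"),
    spot_role = c("antigen", "igg_control", "antigen", "igg_control"),
    intensity = c(100, 0, 100, 500), n_spots = 1L
  )
  expect_error(igg_median_centring(bad_means), "nonpositive")
  # a subarray with no observed IgG at all is reported by name
  bad_means$intensity[2] <- NA
  expect_error(igg_median_centring(bad_means), "X1")
})

test_that("winsorize-to-missing trims per-target tails; oracle agreement", {
  nfi <- tibble::tibble(sample_id = sprintf("X%03d", 1:100))
  set.seed(8)
  nfi$T01 <- sample(1:100)           # 100 distinct values
  nfi$T02 <- rep(7, 100)             # constant target
  nfi$T03 <- c(rnorm(95, 50, 5), rep(NA, 5))
  out <- winsorize_to_missing(nfi)
  expect_identical(sum(is.na(out$T01)), 10L)  # 5 below q5, 5 above q95
  expect_identical(sum(is.na(out$T02)), 0L)

  # sort-and-cut oracle on the column with pre-existing missing values
  obs <- nfi$T03[!is.na(nfi$T03)]
  qs <- quantile(obs, c(0.05, 0.95), names = FALSE)
  expected_missing <- is.na(nfi$T03) | nfi$T03 < qs[1] | nfi$T03 > qs[2]
  expect_identical(is.na(out$T03), expected_missing)
})

test_that("missingness filter drops strictly-greater-than-threshold targets", {
  nfi <- tibble::tibble(sample_id = sprintf("X%03d", 1:240))
  nfi$keep_exact <- c(rep(NA_real_, 60), rnorm(180))   # 25.0% missing
  nfi$drop_over <- c(rep(NA_real_, 61), rnorm(179))    # 25.4% missing
  nfi$complete <- rnorm(240)
  out <- missingness_filter(nfi, 0.25)
  expect_setequal(setdiff(names(out), "sample_id"), c("keep_exact", "complete"))
  # with no missing data the filter is the identity on columns
  full <- nfi[c("sample_id", "complete")]
  expect_identical(names(missingness_filter(full)), names(full))
})

test_that("KNN imputation recovers duplicate and shifted columns, leaves observed cells", {
  nfi <- tibble::tibble(sample_id = sprintf("X%02d", 1:20))
  set.seed(12)
  base <- rnorm(20, 100, 10)
  nfi$T01 <- base
  nfi$T02 <- base          # duplicate column
  nfi$T03 <- base + 50     # parallel-shifted column
  masked <- nfi
  masked$T02[5] <- NA
  masked$T03[9] <- NA
  out <- knn_impute(masked, k = 1)
  expect_equal(out$T02[5], base[5], tolerance = 1e-9)

  # closed form for the 2-column relationship: partner value adjusted by
  # the difference of the columns' co-observed means
  m3 <- mean(masked$T03, na.rm = TRUE)
  m_partner <- mean(masked$T01[!is.na(masked$T03)])
  expect_equal(out$T03[9], base[9] + m3 - m_partner, tolerance = 1e-9)

  # observed cells never altered; no-missing input is identity
  expect_identical(out$T01, nfi$T01)
  expect_identical(as.data.frame(knn_impute(nfi, k = 3))[names(nfi)],
                   as.data.frame(nfi))
})

test_that("pipeline is invariant to a per-subarray multiplicative factor", {
  cfg <- array_sim_config(n_slides = 1, subarrays_per_slide = 8,
                          cohort_sizes = c(4, 4), n_targets = 5,
                          differential_targets = numeric(0), seed = 14)
  sim <- simulate_array_dataset(cfg)
  nfi1 <- preprocess_array(sim$spots)

  scaled <- sim$spots
  igg <- scaled[scaled$spot_role == "igg_control", ]
  med <- tapply(igg$foreground - igg$local_background, igg$subarray_id, median)
  # rescaling any subarray that is not the reference (median) well must
  # leave every NFI unchanged
  pick_id <- as.integer(names(which.max(med)))
  pick <- scaled$subarray_id == pick_id
  scaled$foreground[pick] <- scaled$foreground[pick] * 3
  scaled$local_background[pick] <- scaled$local_background[pick] * 3
  nfi2 <- preprocess_array(scaled)
  expect_identical(names(nfi2), names(nfi1))
  expect_equal(as.matrix(nfi2[-1]), as.matrix(nfi1[-1]), tolerance = 1e-9)
})

test_that("masked NFI entries are recovered within the spot-noise scale", {
  cfg <- array_sim_config(seed = 6)
  sim <- simulate_array_dataset(cfg)
  nfi <- preprocess_array(sim$spots)
  targets <- setdiff(names(nfi), "sample_id")
  log_nfi <- nfi
  for (t in targets) log_nfi[[t]] <- suppressWarnings(log2(nfi[[t]]))

  set.seed(60)
  m <- as.matrix(log_nfi[targets])
  idx <- which(!is.na(m))
  mask <- sample(idx, round(0.05 * length(idx)))
  truth_vals <- m[mask]
  masked <- log_nfi
  mm <- m
  mm[mask] <- NA
  for (j in seq_along(targets)) masked[[targets[j]]] <- mm[, j]
  rec <- knn_impute(masked, k = 5)
  rec_m <- as.matrix(tibble::as_tibble(rec)[targets])
  err <- abs(rec_m[mask] - truth_vals)
  noise_sd_log2 <- cfg$noise_scale_log2 *
    sqrt(cfg$noise_df / (cfg$noise_df - 2))
  expect_lt(median(err), noise_sd_log2)
})

test_that("stage audit log matches a brute-force recount", {
  cfg <- array_sim_config(n_slides = 1, subarrays_per_slide = 8,
                          cohort_sizes = c(4, 4), n_targets = 5, seed = 25)
  sim <- simulate_array_dataset(cfg)
  nfi <- preprocess_array(sim$spots)
  audit <- preprocess_audit(nfi)
  expect_identical(audit$stage,
                   c("igg_median_centring", "winsorize_to_missing",
                     "missingness_filter", "knn_impute"))
  expect_identical(audit$n_missing[4], 0L)
  # recount the winsorization stage by recomputing it directly
  means <- average_replicates(
    subtract_negative_control(net_signal(drop_flagged_spots(sim$spots)))
  )
  raw_nfi <- igg_median_centring(means)
  wz <- winsorize_to_missing(raw_nfi)
  expect_identical(audit$n_missing[2],
                   sum(is.na(as.matrix(wz[setdiff(names(wz), "sample_id")]))))
})
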