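#' Configuration for the antigen-microarray simulator
#'
#' Emulates a custom antigen array: nitrocellulose slides divided into 16
#' incubation wells (subarrays), one serum sample per well, each antigen
#' spotted in triplicate, plus human-IgG positive-control and buffer-blank
#' negative-control spots on every subarray. Spot intensity is multiplicative:
#' subarray batch factor x target level x serum reactivity x heavy-tailed
#' noise, on top of an additive local background. The heavy tail (log2-scale
#' Student-t noise) ensures normality tests reject, so the nonparametric
#' downstream route is the appropriate one.
#'
#' @param n_slides Number of slides.
#' @param subarrays_per_slide Wells per slide (default 16); each well
#'   receives one serum sample, so `n_slides * subarrays_per_slide` must
#'   equal the total cohort size.
#' @param n_targets Number of antigen targets spotted.
#' @param n_replicate_spots Replicate spots per antigen per subarray
#'   (default 3, triplicate printing).
#' @param n_igg_spots Human-IgG positive-control spots per subarray; these
#'   share one global level so median-centring can identify subarray scale.
#' @param n_negctrl_spots Buffer-blank negative-control spots per subarray;
#'   they carry only background plus unspecific secondary-antibody signal.
#' @param cohort_sizes Integer pair `c(cases, controls)` (POAG, CTRL).
#' @param differential_targets Named numeric vector of true log2
#'   location shifts in cases, names being target ids (e.g.
#'   `c(T01 = 1)`); targets default to ids `T01`, `T02`, ...
#' @param subarray_scale_sd SD (log2 scale) of the per-subarray
#'   multiplicative batch factor.
#' @param noise_df Degrees of freedom of the log2-scale t noise; small
#'   values give heavy tails.
#' @param noise_scale_log2 Scale of the spot-level t noise on log2.
#' @param serum_sd_log2 Target-specific between-subject SD of serum
#'   reactivity on log2.
#' @param sample_effect_sd_log2 SD of the per-subject reactivity component
#'   shared across all targets (overall immunoglobulin titer), the source
#'   of between-target correlation.
#' @param seed Integer seed.
#'
#' @return A list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_slides = 15,
                             subarrays_per_slide = 16,
                             n_targets = 9,
                             n_replicate_spots = 3,
                             n_igg_spots = 3,
                             n_negctrl_spots = 3,
                             cohort_sizes = c(120, 120),
                             differential_targets = c(T01 = 1, T02 = 0.8, T03 = 0.6, T04 = 0.6),
                             subarray_scale_sd = 0.35,
                             noise_df = 3,
                             noise_scale_log2 = 0.25,
                             serum_sd_log2 = 0.35,
                             sample_effect_sd_log2 = 0.5,
                             seed = 1L) {
  cfg <- list(
    n_slides = as.integer(n_slides),
    subarrays_per_slide = as.integer(subarrays_per_slide),
    n_targets = as.integer(n_targets),
    n_replicate_spots = as.integer(n_replicate_spots),
    n_igg_spots = as.integer(n_igg_spots),
    n_negctrl_spots = as.integer(n_negctrl_spots),
    cohort_sizes = as.integer(cohort_sizes),
    differential_targets = differential_targets,
    subarray_scale_sd = subarray_scale_sd,
    noise_df = noise_df,
    noise_scale_log2 = noise_scale_log2,
    serum_sd_log2 = serum_sd_log2,
    sample_effect_sd_log2 = sample_effect_sd_log2,
    seed = as.integer(seed)
  )
  class(cfg) <- "array_sim_config"
  validate_array_sim_config(cfg)
  cfg
}

validate_array_sim_config <- function(cfg) {
  n_wells <- cfg$n_slides * cfg$subarrays_per_slide
  if (length(cfg$cohort_sizes) != 2 || any(cfg$cohort_sizes < 2)) {
    abort("invalid `cohort_sizes`: need two counts, each >= 2")
  }
  if (sum(cfg$cohort_sizes) != n_wells) {
    abort(sprintf(
      "invalid `cohort_sizes`: total %d must equal slides x subarrays = %d (one serum per well)",
      sum(cfg$cohort_sizes), n_wells
    ))
  }
  if (cfg$n_targets < 1 || cfg$n_replicate_spots < 1) {
    abort("invalid design: `n_targets` and `n_replicate_spots` must be >= 1")
  }
  if (cfg$n_igg_spots < 1 || cfg$n_negctrl_spots < 1) {
    abort("invalid design: every subarray needs >= 1 IgG and >= 1 negative-control spot")
  }
  tids <- sprintf("T%02d", seq_len(cfg$n_targets))
  extra <- setdiff(names(cfg$differential_targets), tids)
  if (length(cfg$differential_targets) > 0 &&
      (is.null(names(cfg$differential_targets)) || length(extra) > 0)) {
    abort("invalid `differential_targets`: names must be target ids within the simulated panel")
  }
  if (cfg$subarray_scale_sd < 0 || cfg$noise_df <= 0) {
    abort("invalid noise settings: `subarray_scale_sd` >= 0 and `noise_df` > 0 required")
  }
  invisible(cfg)
}

#' Simulate a spotted antigen-microarray cohort
#'
#' Generates a spot-level quantification table (foreground and local
#' background per spot, with grid coordinates), a cohort table (case/control
#' labels plus clinical covariates for cases and a control subgrouping), and
#' the ground truth (differential targets, per-subarray batch factors).
#'
#' Cases carry the configured log2 shifts on the differential targets; the
#' first differential target's reactivity is additionally tied to a latent
#' severity that drives the clinical covariates (cup-disc ratio, visual-field
#' mean deviation, intraocular pressure), so rank correlations between
#' autoantibody level and clinic are recoverable.
#'
#' @param config An [array_sim_config()] object.
#'
#' @return A list with `spots` (tibble: slide_id, subarray_id, sample_id,
#'   block/row/column, target_id, spot_role, replicate_index, foreground,
#'   local_background, flag), `cohort` (sample_id, group, cdr, md, iop,
#'   subgroup) and `truth` (differential target shifts, subarray factors,
#'   IgG level, target levels).
#' @export
#' @examples
#' cfg <- array_sim_config(n_slides = 1, subarrays_per_slide = 4,
#'                         cohort_sizes = c(2, 2), seed = 3)
#' sim <- simulate_array_dataset(cfg)
#' nrow(sim$spots)
simulate_array_dataset <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  validate_array_sim_config(config)
  set.seed(config$seed)

  n_wells <- config$n_slides * config$subarrays_per_slide
  target_ids <- sprintf("T%02d", seq_len(config$n_targets))
  shifts <- stats::setNames(rep(0, config$n_targets), target_ids)
  if (length(config$differential_targets) > 0) {
    shifts[names(config$differential_targets)] <- config$differential_targets
  }

  # wells in slide/subarray order; case/control assignment randomized over wells
  wells <- tibble::tibble(
    slide_id = rep(sprintf("S%02d", seq_len(config$n_slides)),
                   each = config$subarrays_per_slide),
    subarray_id = rep(seq_len(config$subarrays_per_slide), config$n_slides)
  )
  group <- sample(rep(c("POAG", "CTRL"), config$cohort_sizes))
  wells$sample_id <- sprintf("%s%03d", ifelse(group == "POAG", "P", "C"),
                             stats::ave(seq_len(n_wells), group, FUN = seq_along))
  wells$group <- group

  subarray_scale <- 2^rnorm(n_wells, 0, config$subarray_scale_sd)
  igg_level <- 3000
  target_level <- 2^runif(config$n_targets, 8, 11.5)
  names(target_level) <- target_ids
  secondary_level <- 25

  severity <- ifelse(group == "POAG", rnorm(n_wells), NA_real_)

  # serum reactivity per (sample, target) on log2 scale: shared titer
  # component (correlates targets within a subject) + target-specific part
  sample_effect <- rnorm(n_wells, 0, config$sample_effect_sd_log2)
  react <- sample_effect +
    matrix(rnorm(n_wells * config$n_targets, 0, config$serum_sd_log2),
           nrow = n_wells, dimnames = list(wells$sample_id, target_ids))
  for (t in names(shifts)[shifts != 0]) {
    react[group == "POAG", t] <- react[group == "POAG", t] + shifts[t]
  }
  if (any(shifts != 0)) {
    t1 <- names(shifts)[shifts != 0][1]
    react[group == "POAG", t1] <- react[group == "POAG", t1] +
      0.4 * severity[group == "POAG"]
  }

  # spot layout within a subarray: antigens (triplicate), IgG, blanks
  layout <- tibble::tibble(
    target_id = c(rep(target_ids, each = config$n_replicate_spots),
                  sprintf("IgG_%d", seq_len(config$n_igg_spots)),
                  sprintf("NEG_%d", seq_len(config$n_negctrl_spots))),
    spot_role = c(rep("antigen", config$n_targets * config$n_replicate_spots),
                  rep("igg_control", config$n_igg_spots),
                  rep("negative_control", config$n_negctrl_spots)),
    replicate_index = c(rep(seq_len(config$n_replicate_spots), config$n_targets),
                        rep(1L, config$n_igg_spots + config$n_negctrl_spots))
  )
  n_spot <- nrow(layout)
  grid_cols <- 6L
  layout$block <- 1L
  layout$row <- ((seq_len(n_spot) - 1L) %/% grid_cols) + 1L
  layout$column <- ((seq_len(n_spot) - 1L) %% grid_cols) + 1L

  spots <- tidyr::crossing(wells, layout) %>%
    dplyr::arrange(.data$slide_id, .data$subarray_id, .data$row, .data$column)

  idx_well <- match(spots$sample_id, wells$sample_id)
  scale_vec <- subarray_scale[idx_well]

  base_level <- numeric(nrow(spots))
  is_ag <- spots$spot_role == "antigen"
  is_igg <- spots$spot_role == "igg_control"
  is_neg <- spots$spot_role == "negative_control"
  base_level[is_ag] <- target_level[spots$target_id[is_ag]] *
    2^react[cbind(idx_well[is_ag], match(spots$target_id[is_ag], target_ids))]
  base_level[is_igg] <- igg_level
  base_level[is_neg] <- secondary_level

  noise <- 2^(config$noise_scale_log2 * rt(nrow(spots), df = config$noise_df))
  background <- pmax(0, rnorm(nrow(spots), 300, 30))
  foreground <- scale_vec * base_level * noise + background
  foreground <- pmin(foreground, 65535)

  spots$foreground <- foreground
  spots$local_background <- background
  spots$flag <- "ok"
  spots$group <- NULL

  sev <- severity
  cohort <- tibble::tibble(
    sample_id = wells$sample_id,
    group = group,
    cdr = ifelse(group == "POAG",
                 pmin(0.95, pmax(0.2, 0.6 + 0.1 * sev + rnorm(n_wells, 0, 0.1))),
                 NA_real_),
    md = ifelse(group == "POAG",
                -6 - 3 * sev + rnorm(n_wells, 0, 2.5),
                NA_real_),
    iop = ifelse(group == "POAG",
                 pmax(8, 19 + 1 * sev + rnorm(n_wells, 0, 4)),
                 NA_real_)
  )
  # clinical records are incomplete in practice; thin them at typical rates
  for (v in c("cdr", "md", "iop")) {
    miss_rate <- c(cdr = 0.3, md = 0.5, iop = 0.05)[[v]]
    idx <- which(cohort$group == "POAG")
    drop <- sample(idx, round(miss_rate * length(idx)))
    cohort[[v]][drop] <- NA_real_
  }
  ctrl_idx <- cohort$group == "CTRL"
  cohort$subgroup <- NA_character_
  cohort$subgroup[ctrl_idx] <- sample(
    rep(c("other_eye", "systemic", "eye_systemic", "healthy"),
        length.out = sum(ctrl_idx))
  )

  truth <- list(
    differential_target_ids = names(shifts)[shifts != 0],
    shifts = shifts[shifts != 0],
    subarray_factors = tibble::tibble(
      slide_id = wells$slide_id,
      subarray_id = wells$subarray_id,
      sample_id = wells$sample_id,
      scale = subarray_scale
    ),
    igg_level = igg_level,
    target_level = target_level,
    severity = stats::setNames(severity, wells$sample_id)
  )

  list(spots = tibble::as_tibble(spots), cohort = cohort, truth = truth)
}
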