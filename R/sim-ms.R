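#' Default IP-MS screening design
#'
#' Eight-group design of an antibody-mediated antigen capture (IP-MS) screen:
#' two bead-only negative controls (no IgG), two mock controls incubated with
#' lysis buffer instead of cell lysate, and four experimental groups crossing
#' IgG source (patient vs control serum pools) with lysate source (healthy vs
#' glaucomatous trabecular-meshwork cells). Control and mock groups are marked
#' as exclusion groups: any protein detected there is treated as background
#' binding, not antigen capture.
#'
#' @return A tibble with columns `group_id`, `igg_source`, `protein_source`,
#'   `n_replicates` and `exclusion`.
#' @export
default_ms_groups <- function() {
  tibble::tribble(
    ~group_id, ~igg_source, ~protein_source, ~n_replicates, ~exclusion,
    "NC1", "none", "HTM",    1L, TRUE,
    "NC2", "none", "GTM",    1L, TRUE,
    "MA",  "POAG", "buffer", 3L, TRUE,
    "MB",  "CTRL", "buffer", 3L, TRUE,
    "PH",  "POAG", "HTM",    3L, FALSE,
    "PG",  "POAG", "GTM",    3L, FALSE,
    "CH",  "CTRL", "HTM",    3L, FALSE,
    "CG",  "CTRL", "GTM",    3L, FALSE
  )
}

#' Configuration for the IP-MS data simulator
#'
#' @param n_proteins Total number of simulated protein groups.
#' @param n_background_shared Number of proteins that also bind in the
#'   negative/mock control groups (bead or buffer background). These are the
#'   proteins the control-exclusion filter should remove.
#' @param groups Group table as returned by [default_ms_groups()]; may be
#'   replaced by a user design with the same columns.
#' @param n_differential Number of truly differential proteins between the
#'   two lysate sources (applied to non-background proteins).
#' @param effect_log2 True log2 mean difference added to differential proteins
#'   in groups whose `protein_source` equals `effect_source`.
#' @param effect_source Lysate source receiving the shift (default `"GTM"`).
#' @param noise_sd_log2 Replicate-level Gaussian noise SD on the log2 scale.
#' @param censor_quantile Fraction in `[0, 1)`: within each sample, generated
#'   log2 intensities below this quantile are censored to missing. Models the
#'   intensity-dependent (left-censored) missingness of label-free MS, which
#'   is why Gaussian down-shift imputation is the appropriate downstream model.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A list of class `ms_sim_config`.
#' @export
ms_sim_config <- function(n_proteins = 157,
                          n_background_shared = 51,
                          groups = default_ms_groups(),
                          n_differential = 20,
                          effect_log2 = 4,
                          effect_source = "GTM",
                          noise_sd_log2 = 0.5,
                          censor_quantile = 0.15,
                          seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_background_shared = as.integer(n_background_shared),
    groups = tibble::as_tibble(groups),
    n_differential = as.integer(n_differential),
    effect_log2 = effect_log2,
    effect_source = effect_source,
    noise_sd_log2 = noise_sd_log2,
    censor_quantile = censor_quantile,
    seed = as.integer(seed)
  )
  class(cfg) <- "ms_sim_config"
  validate_ms_sim_config(cfg)
  cfg
}

validate_ms_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1) {
    abort("invalid `n_proteins`: must be >= 1")
  }
  if (cfg$n_background_shared > cfg$n_proteins) {
    abort("invalid `n_background_shared`: must not exceed `n_proteins`")
  }
  if (cfg$n_differential > cfg$n_proteins - cfg$n_background_shared) {
    abort("invalid `n_differential`: must not exceed `n_proteins - n_background_shared`")
  }
  needed <- c("group_id", "igg_source", "protein_source", "n_replicates", "exclusion")
  if (!all(needed %in% names(cfg$groups))) {
    abort(paste0("invalid `groups`: needs columns ", paste(needed, collapse = ", ")))
  }
  if (any(cfg$groups$n_replicates < 1)) {
    abort("invalid `groups`: replicate counts must be >= 1")
  }
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1) {
    abort("invalid `censor_quantile`: must be in [0, 1)")
  }
  if (cfg$noise_sd_log2 <= 0 || cfg$effect_log2 < 0) {
    abort("invalid noise or effect size: `noise_sd_log2` > 0, `effect_log2` >= 0 required")
  }
  invisible(cfg)
}

#' Simulate an IP-MS protein quantification experiment
#'
#' Draws per-protein baseline log2 abundances, adds group effects for
#' differential proteins (by lysate source) and replicate-level Gaussian
#' noise, then applies per-sample left-censoring: within each sample the
#' lowest `censor_quantile` fraction of intensities is set missing.
#' Background-shared proteins are quantified in every group including the
#' negative/mock controls; all other proteins are structurally absent from
#' the exclusion groups. iBAQ intensities are the LFQ intensities divided by
#' a per-protein theoretical-peptide count, mimicking how iBAQ rescales
#' summed intensity to a molar quantity.
#'
#' @param config An [ms_sim_config()] object.
#'
#' @return A list with elements
#'   * `quant`: tibble, one row per protein, columns `protein_id`,
#'     `entry_name`, logical flags `reverse`, `contaminant`, `only_site`,
#'     and `lfq_<sample>` / `ibaq_<sample>` intensity columns (`NA` =
#'     not quantified);
#'   * `design`: tibble mapping `sample_id` to group, replicate and sources;
#'   * `truth`: list with the differential protein ids, true effect,
#'     background protein ids, per-sample censoring thresholds (log2) and
#'     the iBAQ divisors.
#' @export
#' @examples
#' sim <- simulate_ms_dataset(ms_sim_config(n_proteins = 40, seed = 7))
#' dim(sim$quant)
simulate_ms_dataset <- function(config) {
  stopifnot(inherits(config, "ms_sim_config"))
  validate_ms_sim_config(config)
  set.seed(config$seed)

  np <- config$n_proteins
  width <- max(4L, nchar(np))
  protein_id <- sprintf(paste0("SIM%0", width, "d"), seq_len(np))
  entry_name <- sprintf("ANT%d_HUMAN", seq_len(np))

  design <- config$groups %>%
    dplyr::rowwise() %>%
    dplyr::reframe(
      sample_id = paste0(.data$group_id, "_", seq_len(.data$n_replicates)),
      group_id = .data$group_id,
      replicate_index = seq_len(.data$n_replicates),
      igg_source = .data$igg_source,
      protein_source = .data$protein_source,
      exclusion = .data$exclusion
    )

  background_ids <- protein_id[seq_len(config$n_background_shared)]
  candidate_ids <- setdiff(protein_id, background_ids)
  diff_ids <- if (config$n_differential > 0) {
    sort(sample(candidate_ids, config$n_differential))
  } else {
    character(0)
  }

  base_log2 <- runif(np, 22, 30)
  ibaq_divisor <- runif(np, 5, 60)

  ns <- nrow(design)
  log2_mat <- matrix(NA_real_, nrow = np, ncol = ns,
                     dimnames = list(protein_id, design$sample_id))
  for (j in seq_len(ns)) {
    present <- if (design$exclusion[j]) protein_id %in% background_ids else rep(TRUE, np)
    mu <- base_log2
    if (!design$exclusion[j] && design$protein_source[j] == config$effect_source) {
      mu[protein_id %in% diff_ids] <- mu[protein_id %in% diff_ids] + config$effect_log2
    }
    vals <- mu + rnorm(np, sd = config$noise_sd_log2)
    vals[!present] <- NA_real_
    log2_mat[, j] <- vals
  }

  # per-sample left-censoring: the faint tail of each run goes undetected
  censor_thresholds <- rep(-Inf, ns)
  if (config$censor_quantile > 0) {
    for (j in seq_len(ns)) {
      obs <- log2_mat[, j]
      thr <- stats::quantile(obs, config$censor_quantile, na.rm = TRUE, names = FALSE)
      censor_thresholds[j] <- thr
      log2_mat[!is.na(obs) & obs < thr, j] <- NA_real_
    }
  }

  lfq <- 2^log2_mat
  ibaq <- sweep(lfq, 1, ibaq_divisor, "/")

  quant <- tibble::tibble(
    protein_id = protein_id,
    entry_name = entry_name,
    reverse = FALSE,
    contaminant = FALSE,
    only_site = FALSE
  )
  lfq_df <- tibble::as_tibble(lfq, .name_repair = "minimal")
  names(lfq_df) <- paste0("lfq_", design$sample_id)
  ibaq_df <- tibble::as_tibble(ibaq, .name_repair = "minimal")
  names(ibaq_df) <- paste0("ibaq_", design$sample_id)
  quant <- dplyr::bind_cols(quant, lfq_df, ibaq_df)

  truth <- list(
    differential_protein_ids = diff_ids,
    effect_log2 = config$effect_log2,
    effect_source = config$effect_source,
    background_protein_ids = background_ids,
    censor_thresholds = tibble::tibble(
      sample_id = design$sample_id,
      threshold_log2 = censor_thresholds
    ),
    ibaq_divisor = stats::setNames(ibaq_divisor, protein_id),
    base_log2 = stats::setNames(base_log2, protein_id)
  )

  list(quant = quant, design = design, truth = truth)
}
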