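#' Simulate a two-genotype cold-stress time-course expression study
#'
#' Draws a genes x samples intensity matrix under a log2-additive model:
#' log2 intensity = gene baseline + planted class effect (a function of
#' genotype, condition and time) + Gaussian replicate noise, exponentiated to
#' the linear scale. One pooled control condition per genotype is simulated
#' (time 0), matching an analysis design in which control collections are
#' pooled rather than kept as separate control timepoints.
#'
#' Planted classes realise their defining inequalities on noiseless means:
#' e.g. `common_induced` genes exceed a 5-fold cold/control ratio in both
#' genotypes whenever `effect_log2 > log2(5)`, and `constitutive_up_il` genes
#' differ more than 5-fold between genotypes at control and at every timepoint
#' while their cold/control ratio stays at 1.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (tibble, first column `gene_id`,
#'   one column per sample, linear scale), `design` (tibble of sample
#'   descriptors), and `truth` (tibble with per-gene class, driver role,
#'   DREB1C-follower flag, and inside/outside-segment placement).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_genes = 50))
#' dim(sim$expression)
#' dplyr::count(sim$truth, class)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- build_design(config)
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  counts <- config$planted_counts
  class_vec <- rep("null", n)
  pos <- 1L
  for (cl in names(counts)) {
    k <- counts[[cl]]
    if (k > 0) {
      class_vec[pos:(pos + k - 1L)] <- cl
      pos <- pos + k
    }
  }

  # driver genes + DREB1C followers live inside the common_induced block
  driver_vec <- rep(NA_character_, n)
  follower_vec <- rep(FALSE, n)
  if (counts[["common_induced"]] >= 3L) {
    driver_vec[1:3] <- c("DREB1A", "DREB1B", "DREB1C")
    nf <- config$n_dreb1c_followers
    if (nf > 0) follower_vec[3L + seq_len(nf)] <- TRUE
  }
  # genes whose cold response follows the DREB1C-analogue pattern
  c_pattern <- follower_vec | (!is.na(driver_vec) & driver_vec == "DREB1C")

  n_t <- length(config$timepoints)
  early <- config$timepoints[seq_len(min(2L, n_t))]
  late <- config$timepoints[seq.int(max(1L, n_t - 1L), n_t)]

  withr::with_seed(config$seed, {
    baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    log2_mat <- matrix(0, nrow = n, ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      log2_mat[, j] <- baseline + planted_effect(
        class_vec, c_pattern,
        genotype = design$genotype[j], condition = design$condition[j],
        time_h = design$time_h[j],
        effect = config$effect_log2, early = early, late = late
      )
    }
    log2_mat <- log2_mat +
      matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd_log2),
             nrow = n)
    in_segment <- stats::runif(n) < config$p_in_segment
  })

  expr <- tibble::as_tibble(
    stats::setNames(as.data.frame(2^log2_mat), design$sample_id)
  )
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), expr)
  attr(expr, "scale") <- "linear"

  truth <- tibble::tibble(
    gene_id = gene_ids,
    class = class_vec,
    driver = driver_vec,
    dreb1c_follower = follower_vec,
    in_segment = in_segment
  )
  list(expression = expr, design = design, truth = truth)
}

#' Sample design table for a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `genotype`, `condition`, `time_h`,
#'   `replicate`; controls carry `time_h = 0`.
#' @export
build_design <- function(config) {
  cells <- dplyr::bind_rows(
    tidyr::expand_grid(genotype = GENOTYPES, condition = "control", time_h = 0),
    tidyr::expand_grid(genotype = GENOTYPES, condition = "cold",
                       time_h = config$timepoints)
  )
  design <- tidyr::expand_grid(cells, replicate = seq_len(config$n_replicates))
  design <- dplyr::arrange(design, match(.data$genotype, GENOTYPES),
                           match(.data$condition, c("control", "cold")),
                           .data$time_h, .data$replicate)
  design$sample_id <- paste(design$genotype, design$condition,
                            design$time_h, design$replicate, sep = "_")
  dplyr::select(design, "sample_id", "genotype", "condition", "time_h", "replicate")
}

# Planted log2 effect for one sample, vectorised over genes.
planted_effect <- function(class_vec, c_pattern, genotype, condition, time_h,
                           effect, early, late) {
  e <- numeric(length(class_vec))
  cold <- condition == "cold"
  il <- genotype == "introgression"

  if (cold) {
    e[class_vec == "common_induced"] <- effect
    e[class_vec == "common_repressed"] <- -effect
    if (!il) {
      e[class_vec == "recurrent_specific_induced"] <- effect
      e[class_vec == "recurrent_specific_repressed"] <- -effect
    } else {
      e[class_vec == "il_specific_induced"] <- effect
      e[class_vec == "il_specific_repressed"] <- -effect
    }
    biphasic <- if (time_h %in% early) -effect else if (time_h %in% late) effect else 0
    e[class_vec == "down_then_up"] <- biphasic
    if (il) e[class_vec == "up_then_down_il"] <- -biphasic
    # DREB1C-analogue pattern: induced throughout in the IL, late-only in the
    # recurrent parent (differential early-phase behaviour between genotypes)
    e[c_pattern] <- if (il || time_h %in% late) effect else 0
  }
  e[class_vec == "constitutive_up_il"] <- if (il) effect else 0
  e[class_vec == "constitutive_down_il"] <- if (il) -effect else 0
  e
}
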