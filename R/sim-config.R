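#' Simulation configuration for the planted-truth generator
#'
#' Defines the study design the generator emulates: two genotypes (a
#' cold-tolerant introgression line and its recurrent parent), one pooled
#' control per genotype plus a five-point cold time course, three biological
#' replicates, and a set of planted truth classes mirroring the six expression
#' pattern groups seen in this kind of time-course experiment (commonly
#' induced/repressed, genotype-specific, constitutive between-genotype
#' differences, and two biphasic patterns).
#'
#' @param seed Integer seed; the whole simulated study is a deterministic
#'   function of it.
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per genotype x condition cell.
#' @param timepoints Cold-stress sampling times in hours, strictly increasing.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline expression on
#'   the log2 intensity scale (linear intensities are `2^log2`).
#' @param noise_sd_log2 Replicate noise SD on the log2 scale.
#' @param effect_log2 Planted effect size in log2 units. The default 3 (an
#'   8-fold change) clears the 5-fold calling gate with margin.
#' @param planted_counts Named integer vector giving the number of genes per
#'   truth class; classes not listed get 0; genes left over are `null`.
#'   Recognised classes: `common_induced`, `common_repressed`,
#'   `recurrent_specific_induced`, `recurrent_specific_repressed`,
#'   `il_specific_induced`, `il_specific_repressed`, `constitutive_up_il`,
#'   `constitutive_down_il`, `down_then_up`, `up_then_down_il`.
#' @param n_dreb1c_followers Number of `common_induced` genes that track the
#'   DREB1C-analogue driver profile (induced from the first timepoint in the
#'   introgression line but only late in the recurrent parent) instead of the
#'   shared flat induction pattern. Three additional `common_induced` genes are
#'   reserved as driver genes (DREB1A/B/C analogues) whenever
#'   `planted_counts["common_induced"] >= 3`.
#' @param motif_plant_rate Fraction of the non-follower `common_induced` genes
#'   that receive at least one planted DRE core word in their promoter
#'   (followers and drivers always get one).
#' @param n_segments Number of introgressed chromosome segments to plant.
#' @param n_qtls Number of cold-tolerance QTL intervals, placed so that they
#'   overlap introgressed segments.
#' @param n_chromosomes,chrom_length Toy genome geometry (bp).
#' @param p_in_segment Probability that a gene is placed inside a planted
#'   segment.
#' @param go_n_terms,go_base_rate,go_enriched_rate,go_enriched_class GO-slim
#'   style annotation: number of flat terms, background annotation rate per
#'   term, planted rate of the designated enriched term within
#'   `go_enriched_class`.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cfg$planted_counts
sim_config <- function(seed,
                       n_genes = 2000L,
                       n_replicates = 3L,
                       timepoints = c(2, 6, 12, 24, 48),
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1,
                       noise_sd_log2 = 0.25,
                       effect_log2 = 3,
                       planted_counts = NULL,
                       n_dreb1c_followers = 20L,
                       motif_plant_rate = 0.3,
                       n_segments = 17L,
                       n_qtls = 31L,
                       n_chromosomes = 12L,
                       chrom_length = 2e6,
                       p_in_segment = 0.08,
                       go_n_terms = 30L,
                       go_base_rate = 0.05,
                       go_enriched_rate = 0.5,
                       go_enriched_class = "il_specific_induced") {
  if (missing(seed)) abort("`seed` is required")
  seed <- as.integer(seed)

  classes <- c(
    "common_induced", "common_repressed",
    "recurrent_specific_induced", "recurrent_specific_repressed",
    "il_specific_induced", "il_specific_repressed",
    "constitutive_up_il", "constitutive_down_il",
    "down_then_up", "up_then_down_il"
  )
  default_counts <- c(
    common_induced = 120L, common_repressed = 40L,
    recurrent_specific_induced = 40L, recurrent_specific_repressed = 30L,
    il_specific_induced = 40L, il_specific_repressed = 30L,
    constitutive_up_il = 30L, constitutive_down_il = 20L,
    down_then_up = 30L, up_then_down_il = 30L
  )
  if (is.null(planted_counts)) planted_counts <- default_counts
  planted_counts <- unlist(planted_counts)
  bad <- setdiff(names(planted_counts), classes)
  if (length(bad) > 0) {
    abort(paste0("unknown truth class(es): ", paste(bad, collapse = ", ")))
  }
  counts <- setNames(integer(length(classes)), classes)
  counts[names(planted_counts)] <- as.integer(planted_counts)
  if (any(counts < 0)) abort("planted counts must be non-negative")
  if (sum(counts) > n_genes) {
    abort("configuration error: planted counts exceed n_genes")
  }
  if (any(diff(timepoints) <= 0)) abort("timepoints must be strictly increasing")
  if (noise_sd_log2 < 0 || baseline_log2_sd < 0) abort("sds must be non-negative")
  if (effect_log2 <= 0) abort("effect_log2 must be strictly positive")
  n_dreb1c_followers <- as.integer(n_dreb1c_followers)
  if (n_dreb1c_followers > 0 && counts[["common_induced"]] < n_dreb1c_followers + 3L) {
    abort("common_induced must hold the 3 drivers plus all dreb1c followers")
  }

  structure(
    list(
      seed = seed, n_genes = as.integer(n_genes),
      n_replicates = as.integer(n_replicates),
      timepoints = timepoints,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      noise_sd_log2 = noise_sd_log2,
      effect_log2 = effect_log2,
      planted_counts = counts,
      n_dreb1c_followers = n_dreb1c_followers,
      motif_plant_rate = motif_plant_rate,
      n_segments = as.integer(n_segments),
      n_qtls = as.integer(n_qtls),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = chrom_length,
      p_in_segment = p_in_segment,
      go_n_terms = as.integer(go_n_terms),
      go_base_rate = go_base_rate,
      go_enriched_rate = go_enriched_rate,
      go_enriched_class = go_enriched_class
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "genes x",
      2L * (1L + length(x$timepoints)) * x$n_replicates, "samples\n")
  planted <- x$planted_counts[x$planted_counts > 0]
  cat("  planted:", paste(names(planted), planted, sep = "=", collapse = ", "),
      "\n  effect_log2 =", x$effect_log2, ", noise_sd_log2 =", x$noise_sd_log2, "\n")
  invisible(x)
}
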