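# Shared fixtures, built in code. The small simulated study is computed once
# per test run and reused across files.

small_cfg <- function(seed = 7, ...) {
  sim_config(
    seed = seed, n_genes = 600,
    planted_counts = c(
      common_induced = 40, common_repressed = 12,
      recurrent_specific_induced = 12, recurrent_specific_repressed = 8,
      il_specific_induced = 12, il_specific_repressed = 8,
      constitutive_up_il = 10, constitutive_down_il = 6,
      down_then_up = 8, up_then_down_il = 8
    ),
    n_dreb1c_followers = 10, ...
  )
}

.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- small_cfg()
    sim <- simulate_dataset(cfg)
    norm <- normalize_arrays(sim$expression)
    det <- detect_expressed(norm)
    degs <- call_degs_all(norm, sim$design, sam_params(seed = 7), det$expressed)
    .fixture_env$study <- list(cfg = cfg, sim = sim, norm = norm, det = det,
                               degs = degs)
  }
  .fixture_env$study
}

# truth-class -> expected called-set membership (by the class definitions:
# biphasic genes are significant in both directions)
expected_set <- function(truth, set, direction) {
  tr <- function(cl) truth$gene_id[truth$class == cl]
  if (set == "common" && direction == "induced") {
    union(tr("common_induced"), tr("down_then_up"))
  } else if (set == "common" && direction == "repressed") {
    union(tr("common_repressed"), tr("down_then_up"))
  } else if (set == "recurrent_specific" && direction == "induced") {
    tr("recurrent_specific_induced")
  } else if (set == "recurrent_specific" && direction == "repressed") {
    tr("recurrent_specific_repressed")
  } else if (set == "il_specific" && direction == "induced") {
    union(tr("il_specific_induced"), tr("up_then_down_il"))
  } else if (set == "il_specific" && direction == "repressed") {
    union(tr("il_specific_repressed"), tr("up_then_down_il"))
  } else {
    stop("unknown set")
  }
}

# a deliberately hand-buildable long DEG table for set-algebra oracles
fake_deg_table <- function(sig_array, genes, times = c(2, 6, 12, 24, 48)) {
  # sig_array: genes x genotype x time x direction logical array
  rows <- list()
  for (g in seq_along(GENOTYPES)) {
    for (t in seq_along(times)) {
      for (d in 1:2) {
        dir <- c("induced", "repressed")[d]
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = genes,
          contrast = paste0(GENOTYPES[g], "_cold_", times[t], "h_vs_control_", dir),
          contrast_type = "cold",
          genotype = GENOTYPES[g],
          time_h = times[t],
          direction = dir,
          significant = sig_array[, g, t, d]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
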