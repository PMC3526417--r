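test_that("timepoints map onto phases I/II/III", {
  expect_equal(assign_phase(c(2, 6)), c("I", "I"))
  expect_equal(assign_phase(12), "II")
  expect_equal(assign_phase(c(24, 48)), c("III", "III"))
  expect_error(assign_phase(3), "2, 6, 12, 24, 48")
})

test_that("definition cases classify as expected", {
  genes <- c("gA", "gB", "gC")
  sig <- array(FALSE, c(3, 2, 5, 2))
  # gA induced in both genotypes at 24 h -> common induced, phase III
  sig[1, 1, 4, 1] <- TRUE; sig[1, 2, 4, 1] <- TRUE
  # gB induced only in the IL at 2 h -> il-specific
  sig[2, 2, 1, 1] <- TRUE
  degs <- fake_deg_table(sig, genes)
  part <- classify_common_specific(degs)
  t <- part$totals
  expect_equal(t$set[t$gene_id == "gA"], "common")
  ph <- part$per_phase
  expect_true(any(ph$gene_id == "gA" & ph$phase == "III" & ph$set == "common"))
  expect_equal(t$set[t$gene_id == "gB"], "il_specific")
  expect_false("gC" %in% t$gene_id)
})

test_that("set algebra over random masks matches a brute-force oracle", {
  withr::with_seed(20, {
    n <- 500
    genes <- sprintf("g%03d", 1:n)
    sig <- array(runif(n * 2 * 5 * 2) < 0.08, c(n, 2, 5, 2))
  })
  degs <- fake_deg_table(sig, genes)
  part <- classify_common_specific(degs)
  phases <- list(I = 1:2, II = 3, III = 4:5)

  for (d in 1:2) {
    dir <- c("induced", "repressed")[d]
    rec_any <- apply(sig[, 1, , d], 1, any)
    il_any <- apply(sig[, 2, , d], 1, any)
    common <- genes[rec_any & il_any]
    rec_only <- genes[rec_any & !il_any]
    il_only <- genes[il_any & !rec_any]
    t <- part$totals[part$totals$direction == dir, ]
    expect_setequal(t$gene_id[t$set == "common"], common)
    expect_setequal(t$gene_id[t$set == "recurrent_specific"], rec_only)
    expect_setequal(t$gene_id[t$set == "il_specific"], il_only)

    for (ph in names(phases)) {
      idx <- phases[[ph]]
      in_ph_rec <- apply(sig[, 1, idx, d, drop = FALSE], 1, any)
      in_ph_il <- apply(sig[, 2, idx, d, drop = FALSE], 1, any)
      pp <- part$per_phase[part$per_phase$direction == dir &
                             part$per_phase$phase == ph, ]
      expect_setequal(pp$gene_id[pp$set == "common"],
                      intersect(common, genes[in_ph_rec | in_ph_il]))
      expect_setequal(pp$gene_id[pp$set == "recurrent_specific"],
                      intersect(rec_only, genes[in_ph_rec]))
      expect_setequal(pp$gene_id[pp$set == "il_specific"],
                      intersect(il_only, genes[in_ph_il]))
    }
  }
})

test_that("union of common and specific sets covers all phase-significant genes", {
  withr::with_seed(21, {
    n <- 300
    genes <- sprintf("g%03d", 1:n)
    sig <- array(runif(n * 2 * 5 * 2) < 0.1, c(n, 2, 5, 2))
  })
  part <- classify_common_specific(fake_deg_table(sig, genes))
  phases <- list(I = 1:2, II = 3, III = 4:5)
  for (d in 1:2) {
    for (ph in names(phases)) {
      idx <- phases[[ph]]
      sig_here <- genes[apply(sig[, , idx, d, drop = FALSE], 1, any)]
      pp <- part$per_phase[part$per_phase$direction ==
                             c("induced", "repressed")[d] &
                             part$per_phase$phase == ph, ]
      # union over the gene's own significant genotype at this phase
      covered <- unique(pp$gene_id)
      expect_true(all(sig_here %in% covered) && all(covered %in% sig_here))
    }
  }
})

test_that("opposite directions in opposite genotypes are flagged as conflicts", {
  genes <- c("gX", "gY")
  sig <- array(FALSE, c(2, 2, 5, 2))
  sig[1, 1, 2, 1] <- TRUE # gX induced in recurrent
  sig[1, 2, 4, 2] <- TRUE # gX repressed in the IL
  sig[2, 2, 1, 1] <- TRUE # gY biphasic within the IL only
  sig[2, 2, 5, 2] <- TRUE
  part <- classify_common_specific(fake_deg_table(sig, genes))
  expect_equal(part$conflicts, "gX")
})

test_that("continuous response requires significance in every phase", {
  genes <- c("g1", "g2")
  sig <- array(FALSE, c(2, 2, 5, 2))
  sig[1, 1, c(1, 3, 4), 1] <- TRUE # 2, 12, 24 h -> all three phases
  sig[2, 1, 1:2, 1] <- TRUE        # 2, 6 h only -> phase I only
  cont <- continuous_response(fake_deg_table(sig, genes))
  expect_equal(cont$gene_id, "g1")

  withr::with_seed(22, {
    n <- 200
    genes <- sprintf("g%03d", 1:n)
    sig <- array(runif(n * 2 * 5 * 2) < 0.25, c(n, 2, 5, 2))
  })
  cont <- continuous_response(fake_deg_table(sig, genes))
  phases <- list(1:2, 3, 4:5)
  for (g in 1:2) {
    for (d in 1:2) {
      oracle <- genes[vapply(seq_len(n), function(i) {
        all(vapply(phases, function(idx) any(sig[i, g, idx, d]), logical(1)))
      }, logical(1))]
      got <- cont$gene_id[cont$genotype == GENOTYPES[g] &
                            cont$direction == c("induced", "repressed")[d]]
      expect_setequal(got, oracle)
    }
  }
})

test_that("dropping a timepoint can only shrink the continuous sets", {
  withr::with_seed(23, {
    n <- 150
    genes <- sprintf("g%03d", 1:n)
    sig <- array(runif(n * 2 * 5 * 2) < 0.3, c(n, 2, 5, 2))
  })
  full <- continuous_response(fake_deg_table(sig, genes))
  degs <- fake_deg_table(sig, genes)
  reduced <- continuous_response(degs[degs$time_h != 24, ])
  key <- function(x) paste(x$genotype, x$direction, x$gene_id)
  expect_true(all(key(reduced) %in% key(full)))
})

test_that("constitutive DEGs are control-significant and never cold-responsive", {
  st <- small_study()
  const <- constitutive_degs(st$degs)
  d <- tibble::as_tibble(st$degs)
  ctrl_sig <- d[d$contrast == "il_vs_recurrent_control" & d$significant, ]
  cold_resp <- unique(d$gene_id[d$contrast_type == "cold" & d$significant])
  oracle_up <- ctrl_sig$gene_id[!ctrl_sig$gene_id %in% cold_resp &
                                  ctrl_sig$direction == "induced"]
  oracle_down <- ctrl_sig$gene_id[!ctrl_sig$gene_id %in% cold_resp &
                                    ctrl_sig$direction == "repressed"]
  expect_setequal(const$gene_id[const$set == "constitutive_up_il"], oracle_up)
  expect_setequal(const$gene_id[const$set == "constitutive_down_il"], oracle_down)
  # planted constitutive genes (up 8x at control and every timepoint, no cold
  # response) are recovered; cold-only genes are excluded
  truth <- st$sim$truth
  expect_true(all(truth$gene_id[truth$class == "constitutive_up_il"] %in%
                    const$gene_id[const$set == "constitutive_up_il"]))
  expect_false(any(truth$gene_id[truth$class == "common_induced"] %in%
                     const$gene_id))
})

test_that("mismatched gene universes are rejected", {
  st <- small_study()
  d <- tibble::as_tibble(st$degs)
  broken <- d[-1, ]
  expect_error(classify_common_specific(broken), "mismatched gene universes")
})
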