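test_that("promoter extraction follows the -1000..-10 window on both strands", {
  withr::with_seed(40, chr <- paste(sample(c("A", "C", "G", "T"), 6000,
                                           replace = TRUE), collapse = ""))
  genome <- c(chr1 = chr)
  plus <- tibble::tibble(chrom = "chr1", start = 5000, end = 5600,
                         name = "gp", strand = "+")
  got <- extract_promoters(plus, genome)
  expect_equal(nchar(got$sequence), 991)
  expect_identical(got$sequence, substr(chr, 4001, 4991))
  expect_false(got$truncated)

  minus <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000,
                          name = "gm", strand = "-")
  gotm <- extract_promoters(minus, genome)
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 2010, 3000))
  ))
  expect_identical(gotm$sequence, oracle)

  near <- tibble::tibble(chrom = "chr1", start = 500, end = 900,
                         name = "gt", strand = "+")
  expect_warning(gott <- extract_promoters(near, genome), "truncated")
  expect_equal(nchar(gott$sequence), 491)

  off <- tibble::tibble(chrom = "chr1", start = 5000, end = 7000,
                        name = "go", strand = "+")
  expect_error(extract_promoters(off, genome), "off its chromosome")
})

test_that("the scanner finds direct matches and empty sequences give none", {
  hits <- scan_dre(tibble::tibble(gene_id = "g1", sequence = "TTGCCGACTT"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$word, "GCCGAC")
  none <- scan_dre(tibble::tibble(gene_id = "g1",
                                  sequence = strrep("AT", 100)))
  expect_equal(nrow(none), 0)
})

test_that("the scanner equals a naive sliding-window oracle on random promoters", {
  withr::with_seed(41, seqs <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 991, replace = TRUE), collapse = "")
  }, character(1)))
  prom <- tibble::tibble(gene_id = sprintf("p%03d", 1:200), sequence = seqs)
  got <- scan_dre(prom)
  for (i in seq_len(200)) {
    oracle <- scan_oracle(seqs[i])
    g <- got[got$gene_id == prom$gene_id[i], c("offset", "strand", "word")]
    if (nrow(oracle) == 0) {
      expect_equal(nrow(g), 0)
    } else {
      expect_equal(dplyr::arrange(g, .data$offset, .data$word),
                   dplyr::arrange(oracle, .data$offset, .data$word))
    }
  }
})

test_that("scanning the reverse complement swaps strands (involution)", {
  withr::with_seed(42, seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  }, character(1)))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  fwd <- scan_dre(tibble::tibble(gene_id = as.character(1:30), sequence = seqs))
  rev <- scan_dre(tibble::tibble(gene_id = as.character(1:30), sequence = rc))
  flip <- dplyr::mutate(rev,
                        offset = 500L - 6L - .data$offset,
                        strand = dplyr::if_else(.data$strand == "+", "-", "+"))
  key <- function(x) sort(paste(x$gene_id, x$offset, x$strand))
  expect_identical(key(fwd), key(flip))
})

test_that("regulon membership and driver co-expression behave on planted data", {
  st <- small_study()
  truth <- st$sim$truth
  pr <- simulate_promoters(truth, st$cfg)
  hits <- scan_dre(pr$promoters)
  part <- classify_common_specific(st$degs)
  common_ind <- part$totals$gene_id[part$totals$set == "common" &
                                      part$totals$direction == "induced"]
  drivers <- setNames(truth$gene_id[!is.na(truth$driver)],
                      truth$driver[!is.na(truth$driver)])
  reg <- assign_regulons(common_ind, hits, st$norm, st$sim$design, drivers)

  # regulon contract: subset of common-induced, every member has a hit
  expect_true(all(reg$gene_id %in% common_ind))
  expect_true(all(reg$n_dre_hits[reg$in_dreb1_regulon] >= 1))
  expect_lte(sum(reg$in_dreb1_regulon), length(common_ind))

  # exactly the planted DREB1C followers are DREB1C-specific
  expect_setequal(reg$gene_id[reg$dreb1c_specific],
                  truth$gene_id[truth$dreb1c_follower])

  # plain common-induced regulon members track the shared drivers
  plain <- truth$gene_id[truth$class == "common_induced" &
                           !truth$dreb1c_follower & is.na(truth$driver)]
  shared <- reg$in_dreb1_regulon & reg$gene_id %in% plain
  expect_true(all(reg$coex_DREB1A[shared]))
  expect_error(assign_regulons(common_ind, hits, st$norm, st$sim$design,
                               c(DREB1A = "nope", DREB1B = "x", DREB1C = "y")),
               "missing")
})

test_that("a gene matching a driver profile exactly is co-expressed; flat profiles are flagged", {
  st <- small_study()
  truth <- st$sim$truth
  drivers <- setNames(truth$gene_id[!is.na(truth$driver)],
                      truth$driver[!is.na(truth$driver)])
  # clone the DREB1C driver row into a spare null gene and flatten another
  expr <- st$norm
  null_ids <- truth$gene_id[truth$class == "null"][1:2]
  expr[expr$gene_id == null_ids[1], -1] <-
    expr[expr$gene_id == drivers[["DREB1C"]], -1]
  expr[expr$gene_id == null_ids[2], -1] <- as.list(rep(100, ncol(expr) - 1))
  attr(expr, "scale") <- "linear"
  hits <- tibble::tibble(gene_id = null_ids, offset = 0L,
                         strand = "+", word = "GCCGAC")
  reg <- assign_regulons(null_ids, hits, expr, st$sim$design, drivers)
  expect_equal(reg$r_DREB1C[1], 1)
  expect_true(reg$coex_DREB1C[1])
  expect_true(reg$flat_profile[2])
  expect_true(is.na(reg$r_DREB1C[2]))
  expect_false(reg$dreb1c_specific[2])
})
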