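#' Simulate promoter sequences with planted DRE core motifs
#'
#' Emits one 991-nt promoter per gene (the -1000..-10 window relative to the
#' start codon) with uniform A/C/G/T background. Genes of the `common_induced`
#' truth class are the designated motif set: driver and DREB1C-follower genes
#' always receive one planted DRE core word (`GCCGAC` or `ACCGAC`), the rest
#' with probability `motif_plant_rate`. Accidental background occurrences are
#' allowed (and found by the scanner); the returned motif truth records only
#' planted words.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param config The same [sim_config()].
#' @param reject_background_hits If `TRUE`, background sequences are redrawn
#'   until they contain no DRE word on either strand (useful for toy cases
#'   where the scanner must find exactly the planted hits). Default `FALSE`.
#' @return List with `promoters` (tibble `gene_id`, `sequence`) and
#'   `motif_truth` (tibble `gene_id`, `offset` 0-based, `word`).
#' @export
simulate_promoters <- function(truth, config, reject_background_hits = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  width <- 991L
  words <- c("GCCGAC", "ACCGAC")
  all_words <- c(words, revcomp(words))
  n <- nrow(truth)

  designated <- truth$class == "common_induced"
  always <- truth$dreb1c_follower | !is.na(truth$driver)

  withr::with_seed(config$seed + 1L, {
    plant <- designated &
      (always | stats::runif(n) < config$motif_plant_rate)
    seqs <- character(n)
    for (i in seq_len(n)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                   collapse = "")
        if (!reject_background_hits ||
            !any(vapply(all_words, grepl, logical(1), x = s, fixed = TRUE))) break
      }
      seqs[i] <- s
    }
    offsets <- rep(NA_integer_, n)
    planted_word <- rep(NA_character_, n)
    idx <- which(plant)
    if (length(idx) > 0) {
      offsets[idx] <- sample.int(width - 6L + 1L, length(idx), replace = TRUE) - 1L
      planted_word[idx] <- sample(words, length(idx), replace = TRUE)
      for (i in idx) {
        substr(seqs[i], offsets[i] + 1L, offsets[i] + 6L) <- planted_word[i]
      }
    }
  })

  list(
    promoters = tibble::tibble(gene_id = truth$gene_id, sequence = seqs),
    motif_truth = tibble::tibble(
      gene_id = truth$gene_id[plant],
      offset = offsets[plant],
      word = planted_word[plant]
    )
  )
}

# reverse complement of DNA words (character vector)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
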