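#' Extract promoter windows from a genome
#'
#' The promoter window spans -1000..-10 relative to the start codon (991 nt).
#' For + strand genes this is the 991 bases ending 10 bp before the gene
#' start; for - strand genes, the reverse complement of the 991 bases
#' starting 10 bp after the gene end. Windows running off the chromosome
#' edge are truncated with a warning.
#'
#' @param genes Interval tibble (`chrom`, `start`, `end`, `name`, `strand`;
#'   0-based half-open).
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @return Tibble with `gene_id`, `sequence`, `truncated`.
#' @export
extract_promoters <- function(genes, genome) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  chr_len <- setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(genes$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) not in genome: ", paste(missing, collapse = ", ")))
  }
  n <- nrow(genes)
  seqs <- character(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    len <- chr_len[[genes$chrom[i]]]
    if (genes$start[i] < 0 || genes$end[i] > len) {
      abort(paste0("gene '", genes$name[i], "' lies off its chromosome"))
    }
    if (genes$strand[i] == "-") {
      # upstream of the start codon at the gene's right edge
      lo <- genes$end[i] + 9
      hi <- genes$end[i] + 1000
      w_lo <- lo
      w_hi <- min(hi, len)
    } else {
      lo <- genes$start[i] - 1000
      hi <- genes$start[i] - 9
      w_lo <- max(lo, 0)
      w_hi <- hi
    }
    truncated[i] <- w_hi - w_lo < 991
    if (w_hi <= w_lo) {
      seqs[i] <- ""
      next
    }
    sub <- Biostrings::subseq(genome[[genes$chrom[i]]], w_lo + 1, w_hi)
    if (genes$strand[i] == "-") sub <- Biostrings::reverseComplement(sub)
    seqs[i] <- as.character(sub)
  }
  if (any(truncated)) {
    warn(paste0(sum(truncated), " promoter window(s) truncated at a chromosome edge"))
  }
  tibble::tibble(gene_id = genes$name, sequence = seqs, truncated = truncated)
}

DRE_WORDS <- c("GCCGAC", "ACCGAC")

#' Scan promoters for the DRE core motif
#'
#' Reports every occurrence (overlaps included) of the DRE core words
#' `GCCGAC` and `ACCGAC` on the given sequence and, in both-strands mode
#' (default), of their reverse complements `GTCGGC` / `GTCGGT` as - strand
#' hits.
#'
#' @param promoters Tibble with `gene_id` and `sequence` (or a single
#'   character vector of sequences).
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Tibble with `gene_id`, `offset` (0-based within the window),
#'   `strand`, `word` (the matched text as it appears on the sequence).
#' @export
#' @examples
#' scan_dre(tibble::tibble(gene_id = "g1", sequence = "TTGCCGACTT"))
scan_dre <- function(promoters, both_strands = TRUE) {
  if (is.character(promoters)) {
    promoters <- tibble::tibble(
      gene_id = names(promoters) %||% as.character(seq_along(promoters)),
      sequence = unname(promoters)
    )
  }
  words <- DRE_WORDS
  if (both_strands) words <- c(words, revcomp(DRE_WORDS))
  strands <- rep(c("+", "-"), each = 2)[seq_along(words)]

  hits <- list()
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  for (w in seq_along(words)) {
    m <- Biostrings::vmatchPattern(words[w], seqs)
    starts <- Biostrings::startIndex(m)
    for (i in seq_along(starts)) {
      st <- starts[[i]]
      if (is.null(st) || length(st) == 0) next
      hits[[length(hits) + 1L]] <- tibble::tibble(
        gene_id = promoters$gene_id[i],
        offset = st - 1L,
        strand = strands[w],
        word = words[w]
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(gene_id = character(0), offset = integer(0),
                          strand = character(0), word = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(hits),
                 match(.data$gene_id, promoters$gene_id), .data$offset)
}

#' Assign commonly induced genes to the DREB1 regulon
#'
#' A gene belongs to the DREB1 regulon when it is commonly cold-induced and
#' carries at least one DRE core motif in its promoter window. For each gene,
#' Pearson correlation with each driver gene is computed over the
#' concatenated genotype-wise time-course of replicate-mean log2 values
#' (control then each cold timepoint, recurrent parent then introgression
#' line); `coexpressed` uses the strict cutoff r > 0.9. A gene is
#' `dreb1c_specific` when it is in the regulon, co-expressed with the DREB1C
#' driver and with neither of the other two drivers.
#'
#' @param common_induced Character vector of commonly induced gene ids.
#' @param hits Motif-hit tibble from [scan_dre()].
#' @param expr Normalized linear-scale expression tibble.
#' @param design Design tibble.
#' @param drivers Named character vector of driver gene ids, names
#'   `DREB1A`, `DREB1B`, `DREB1C`.
#' @return Tibble with `gene_id`, `n_dre_hits`, `in_dreb1_regulon`,
#'   `r_DREB1A`/`r_DREB1B`/`r_DREB1C`, `coex_*` logicals, `flat_profile`,
#'   `dreb1c_specific`.
#' @export
assign_regulons <- function(common_induced, hits, expr, design,
                            drivers) {
  need <- c("DREB1A", "DREB1B", "DREB1C")
  if (!all(need %in% names(drivers))) {
    abort("drivers must be named DREB1A, DREB1B, DREB1C")
  }
  if (!all(drivers %in% expr$gene_id)) {
    abort("driver gene(s) missing from the expression matrix")
  }
  prof <- profile_matrix(expr, design)
  # the drivers are the regulators, not regulon members
  genes <- setdiff(intersect(common_induced, rownames(prof)), drivers)
  n_hits <- table(factor(hits$gene_id, levels = genes))

  r <- matrix(NA_real_, nrow = length(genes), ncol = 3,
              dimnames = list(genes, need))
  flat <- logical(length(genes))
  for (k in seq_along(need)) {
    dp <- prof[drivers[[need[k]]], ]
    for (i in seq_along(genes)) {
      gp <- prof[genes[i], ]
      if (sd(gp) == 0 || sd(dp) == 0) {
        flat[i] <- flat[i] || sd(gp) == 0
        next
      }
      r[i, k] <- cor(gp, dp)
    }
  }
  coex <- !is.na(r) & r > 0.9
  in_reg <- as.integer(n_hits) >= 1L

  tibble::tibble(
    gene_id = genes,
    n_dre_hits = as.integer(n_hits),
    in_dreb1_regulon = in_reg,
    r_DREB1A = unname(r[, 1]), r_DREB1B = unname(r[, 2]),
    r_DREB1C = unname(r[, 3]),
    coex_DREB1A = coex[, 1], coex_DREB1B = coex[, 2], coex_DREB1C = coex[, 3],
    flat_profile = flat,
    dreb1c_specific = in_reg & coex[, 3] & !coex[, 1] & !coex[, 2]
  )
}
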