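#' Simulate a toy genome annotation with planted introgressed segments
#'
#' Lays out a 12-chromosome toy genome carrying `n_segments` pairwise disjoint
#' introgressed segments, places every gene consistently with the truth
#' table's inside/outside-segment flag, plants cold-tolerance QTL intervals
#' overlapping the segments, and draws a flat GO-slim style annotation in
#' which one designated term is strongly enriched within one truth class.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param config The same [sim_config()].
#' @return List with `genes`, `segments`, `qtls` (interval tibbles with
#'   `chrom`, `start`, `end`, `name`, `kind`; genes also carry `strand`;
#'   coordinates 0-based half-open) and `go` (tibble `term`, `description`,
#'   `genes` list-column).
#' @export
simulate_annotation <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n_chr <- config$n_chromosomes
  len <- config$chrom_length
  chroms <- sprintf("chr%02d", seq_len(n_chr))
  n_seg <- config$n_segments
  gene_len <- 3000

  withr::with_seed(config$seed + 2L, {
    # segments: round-robin over chromosomes, each inside its own half-slot,
    # so disjointness holds by construction (at most 2 per chromosome)
    seg_chr_idx <- ((seq_len(n_seg) - 1L) %% n_chr) + 1L
    slot <- ((seq_len(n_seg) - 1L) %/% n_chr)
    if (any(slot > 1L)) abort("n_segments must be <= 2 * n_chromosomes")
    seg_len <- round(stats::runif(n_seg, 1e5, 2.5e5))
    slot_lo <- slot * len / 2
    seg_start <- round(slot_lo + stats::runif(n_seg) * (len / 2 - seg_len))
    segments <- tibble::tibble(
      chrom = chroms[seg_chr_idx],
      start = seg_start, end = seg_start + seg_len,
      name = sprintf("seg%02d", seq_len(n_seg)), kind = "segment"
    )

    # genes: planted inside a random segment, or uniformly outside them
    n <- nrow(truth)
    g_chrom <- character(n)
    g_start <- numeric(n)
    for (i in seq_len(n)) {
      if (truth$in_segment[i] && n_seg > 0) {
        s <- sample.int(n_seg, 1L)
        g_chrom[i] <- segments$chrom[s]
        g_start[i] <- round(segments$start[s] +
          stats::runif(1) * (seg_len[s] - gene_len))
      } else {
        repeat {
          ci <- sample.int(n_chr, 1L)
          st <- round(stats::runif(1) * (len - gene_len))
          hit <- segments$chrom == chroms[ci] &
            pmax(segments$start, st) < pmin(segments$end, st + gene_len)
          if (!any(hit)) break
        }
        g_chrom[i] <- chroms[ci]
        g_start[i] <- st
      }
    }
    genes <- tibble::tibble(
      chrom = g_chrom, start = g_start, end = g_start + gene_len,
      name = truth$gene_id, kind = "gene",
      strand = sample(c("+", "-"), n, replace = TRUE)
    )

    # QTLs overlap a subset of the segments (at most 15 distinct segments)
    n_qtl <- config$n_qtls
    qtls <- tibble::tibble(chrom = character(0), start = numeric(0),
                           end = numeric(0), name = character(0),
                           kind = character(0))
    if (n_qtl > 0 && n_seg > 0) {
      host_pool <- sample.int(n_seg, min(15L, n_seg))
      host <- host_pool[((seq_len(n_qtl) - 1L) %% length(host_pool)) + 1L]
      q_len <- 4e5
      q_start <- pmax(0, segments$start[host] - round(stats::runif(n_qtl, 0, 1.5e5)))
      q_end <- pmin(len, q_start + q_len)
      qtls <- tibble::tibble(
        chrom = segments$chrom[host], start = q_start, end = q_end,
        name = sprintf("qtl%02d", seq_len(n_qtl)), kind = "qtl"
      )
    }

    # flat GO-slim style annotation; term GO:0001 is planted enriched
    terms <- sprintf("GO:%04d", seq_len(config$go_n_terms))
    in_class <- truth$class == config$go_enriched_class
    members <- vector("list", config$go_n_terms)
    annot <- matrix(stats::runif(n * config$go_n_terms) < config$go_base_rate,
                    nrow = n)
    annot[in_class, 1L] <- stats::runif(sum(in_class)) < config$go_enriched_rate
    # cap at 5 terms per gene (keep lowest-numbered terms, incl. the planted one)
    for (i in which(rowSums(annot) > 5L)) {
      keep <- which(annot[i, ])[1:5]
      annot[i, ] <- FALSE
      annot[i, keep] <- TRUE
    }
    for (t in seq_along(terms)) members[[t]] <- truth$gene_id[annot[, t]]
  })

  go <- tibble::tibble(
    term = terms,
    description = c("planted_enriched", rep("background", length(terms) - 1L)),
    genes = members
  )
  list(genes = genes, segments = segments, qtls = qtls, go = go)
}
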