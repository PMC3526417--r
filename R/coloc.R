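#' Overlapping pairs between two interval sets
#'
#' Intervals are 0-based half-open; a pair overlaps iff it shares a
#' chromosome and `max(starts) < min(ends)` (so abutting intervals do not
#' overlap).
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`, `name`).
#' @return Tibble with `name_a`, `name_b`, `chrom`, `overlap` (bp) and
#'   `contained` (a entirely inside b).
#' @export
intersect_intervals <- function(set_a, set_b) {
  a <- dplyr::select(tibble::as_tibble(set_a), "chrom",
                     start_a = "start", end_a = "end", name_a = "name")
  b <- dplyr::select(tibble::as_tibble(set_b), "chrom",
                     start_b = "start", end_b = "end", name_b = "name")
  pairs <- dplyr::inner_join(a, b, by = "chrom", relationship = "many-to-many")
  pairs <- dplyr::filter(pairs,
                         pmax(.data$start_a, .data$start_b) <
                           pmin(.data$end_a, .data$end_b))
  dplyr::transmute(
    pairs,
    name_a = .data$name_a, name_b = .data$name_b, chrom = .data$chrom,
    overlap = pmin(.data$end_a, .data$end_b) - pmax(.data$start_a, .data$start_b),
    contained = .data$start_a >= .data$start_b & .data$end_a <= .data$end_b
  )
}

#' Co-localization of DEGs and QTLs with introgressed segments
#'
#' Intersects DEG gene loci and QTL intervals with the introgressed
#' chromosome segments and reports, per segment, the overlapping DEGs (with
#' their set labels) and QTLs; DEGs overlapping no segment are listed
#' separately as unlinked.
#'
#' @param deg_sets Tibble with `gene_id` and `set` (labels from the temporal
#'   classification) for the genes to place.
#' @param gene_intervals Interval tibble for (at least) those genes; DEGs
#'   with no interval are reported as unplaced.
#' @param segments,qtls Interval tibbles.
#' @param flank Symmetric flank in bp widening each segment ("near"; default 0).
#' @return A list of class `coloc_report`: `per_segment` (tibble `segment`,
#'   `chrom`, `start`, `end`, `n_degs`, `n_qtls`, plus `degs`/`qtls`
#'   list-columns), `in_segment` (gene-level pairs with set labels),
#'   `unlinked` (placed DEGs overlapping no segment), `unplaced` (DEGs with
#'   no interval).
#' @export
colocalization_report <- function(deg_sets, gene_intervals, segments, qtls,
                                  flank = 0) {
  segs <- tibble::as_tibble(segments)
  widened <- dplyr::mutate(segs, start = pmax(0, .data$start - flank),
                           end = .data$end + flank)
  placed <- dplyr::filter(gene_intervals, .data$name %in% deg_sets$gene_id)
  unplaced <- setdiff(deg_sets$gene_id, gene_intervals$name)

  gene_pairs <- intersect_intervals(placed, widened)
  gene_pairs <- dplyr::left_join(
    dplyr::rename(gene_pairs, gene_id = "name_a", segment = "name_b"),
    deg_sets, by = "gene_id", relationship = "many-to-many"
  )
  qtl_pairs <- intersect_intervals(qtls, widened)

  per_segment <- dplyr::transmute(
    segs, segment = .data$name, chrom = .data$chrom,
    start = .data$start, end = .data$end
  )
  per_segment$degs <- map(per_segment$segment, function(s) {
    sort(unique(gene_pairs$gene_id[gene_pairs$segment == s]))
  })
  per_segment$qtls <- map(per_segment$segment, function(s) {
    sort(unique(qtl_pairs$name_a[qtl_pairs$name_b == s]))
  })
  per_segment$n_degs <- lengths(per_segment$degs)
  per_segment$n_qtls <- lengths(per_segment$qtls)

  structure(
    list(per_segment = per_segment,
         in_segment = dplyr::arrange(gene_pairs, .data$segment, .data$gene_id),
         unlinked = sort(setdiff(placed$name, gene_pairs$gene_id)),
         unplaced = sort(unplaced)),
    class = "coloc_report"
  )
}

#' @export
print.coloc_report <- function(x, ...) {
  cat("<coloc_report>", nrow(x$per_segment), "segments;",
      length(unique(x$in_segment$gene_id)), "DEG(s) on segments;",
      length(x$unlinked), "unlinked;", length(x$unplaced), "unplaced\n")
  invisible(x)
}

#' @export
tidy.coloc_report <- function(x, ...) {
  dplyr::select(x$per_segment, "segment", "chrom", "start", "end",
                "n_degs", "n_qtls")
}
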