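#' FASTA input and output
#'
#' Reading uppercases sequences and rejects symbols outside A/C/G/T/N.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(name = character(0), sequence = character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("FASTA format error: record '", names(set)[bad][1],
                 "' contains non-ACGTN symbols"))
  }
  tibble::tibble(name = names(set), sequence = unname(seqs))
}

#' @rdname read_fasta
#' @param records Tibble with `name`/`sequence` columns (a `gene_id` column is
#'   accepted in place of `name`).
#' @export
write_fasta <- function(records, path) {
  nm <- if ("name" %in% names(records)) records$name else records$gene_id
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' BED interval input and output
#'
#' Internal coordinates are 0-based half-open (BED native). An import mode
#' converts 1-based inclusive tables (marker-interval style) on the way in.
#'
#' @param path BED path (4+ columns, no header).
#' @param kind Interval kind tag: `"gene"`, `"segment"` or `"qtl"`.
#' @param coords `"bed"` (0-based half-open, default) or `"one_based"`
#'   (1-based inclusive, converted on read).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `kind` and, when a
#'   6th column is present, `strand`.
#' @export
read_bed <- function(path, kind = c("gene", "segment", "qtl"),
                     coords = c("bed", "one_based")) {
  kind <- match.arg(kind)
  coords <- match.arg(coords)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 4) abort("BED format error: fewer than 4 columns")
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    name = raw[[4]],
    kind = kind
  )
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  if (anyNA(out$start) || anyNA(out$end)) {
    abort("BED format error: non-numeric coordinate")
  }
  if (coords == "one_based") out$start <- out$start - 1
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad) > 0) {
    abort(paste0("BED format error: start >= end for record '",
                 out$name[bad[1]], "'"))
  }
  out
}

#' @rdname read_bed
#' @param intervals Interval tibble as returned by [read_bed()].
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[c("chrom", "start", "end", "name")]
  if ("strand" %in% names(intervals)) {
    cols$score <- 0L
    cols$strand <- intervals$strand
  }
  readr::write_tsv(cols, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Coordinate convention conversions
#'
#' `to_one_based()` and `to_zero_based()` convert interval starts between the
#' internal 0-based half-open convention and 1-based inclusive tables; they
#' are mutual inverses.
#'
#' @param intervals Interval tibble.
#' @export
to_one_based <- function(intervals) {
  intervals$start <- intervals$start + 1
  intervals
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(intervals) {
  intervals$start <- intervals$start - 1
  intervals
}

#' GMT gene-set input and output
#'
#' One term per line: term, description, then gene ids, tab-separated.
#' Duplicate gene ids within a term are collapsed on read.
#'
#' @param path GMT path.
#' @return Tibble with `term`, `description` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) abort("GMT format error: line with fewer than 2 fields")
  tibble::tibble(
    term = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param gmt Tibble with `term`, `description`, `genes` list-column.
#' @export
write_gmt <- function(gmt, path) {
  lines <- pmap(gmt[c("term", "description", "genes")],
                function(term, description, genes) {
                  paste(c(term, description, genes), collapse = "\t")
                })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}
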