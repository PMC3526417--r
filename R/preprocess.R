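#' Presence calling on a linear-intensity matrix
#'
#' A gene is called expressed when its intensity reaches `threshold` in at
#' least one sample (inclusive), mirroring the "expressed in at least one
#' sample" rule used to restrict downstream testing to detectable genes.
#'
#' @param expr Linear-scale expression tibble.
#' @param threshold Linear intensity threshold (default 100).
#' @return List with `detection` (tibble of gene x sample logicals, same
#'   shape as `expr`) and `expressed` (character vector of gene ids).
#' @export
detect_expressed <- function(expr, threshold = 100) {
  if (expr_scale(expr) != "linear") {
    abort("detect_expressed() requires a linear-scale matrix")
  }
  m <- expr_matrix(expr)
  det <- m >= threshold
  detection <- dplyr::bind_cols(tibble::tibble(gene_id = expr$gene_id),
                                tibble::as_tibble(det))
  attr(detection, "threshold") <- threshold
  list(detection = detection,
       expressed = expr$gene_id[rowSums(det) > 0])
}

#' Per-array median scaling
#'
#' Rescales every array (sample column) so its median equals the global
#' median of per-array medians, a deliberately simple array-effect
#' normalization for linear intensities. The operation is idempotent.
#'
#' @param expr Linear-scale expression tibble.
#' @return Normalized linear-scale expression tibble.
#' @export
normalize_arrays <- function(expr) {
  if (expr_scale(expr) != "linear") {
    abort("normalize_arrays() requires a linear-scale matrix")
  }
  m <- expr_matrix(expr)
  if (any(m < 0)) abort("negative intensities cannot be normalized")
  med <- apply(m, 2, median)
  if (any(med <= 0)) abort("a sample has non-positive median intensity")
  target <- median(med)
  m <- sweep(m, 2, target / med, `*`)
  expr_from_matrix(m, "linear")
}

#' Log2 view of a linear matrix
#'
#' @param expr Linear-scale expression tibble.
#' @param pseudocount Added before taking log2 (default 1 on the linear
#'   scale); with `pseudocount = 0`, non-positive values are an error.
#' @return Expression tibble on the log2 scale.
#' @export
log2_view <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) != "linear") abort("log2_view() requires a linear matrix")
  m <- expr_matrix(expr)
  if (pseudocount == 0 && any(m <= 0)) {
    abort("non-positive values with pseudocount 0")
  }
  expr_from_matrix(log2(m + pseudocount), "log2")
}

#' Per-gene linear fold change between two sample groups
#'
#' `FC = mean(group_a) / mean(group_b)` on the linear scale; genes with
#' `FC > 1` are induced (a relative to b).
#'
#' @param expr Linear-scale expression tibble.
#' @param samples_a,samples_b Disjoint, non-empty character vectors of sample
#'   ids (columns of `expr`).
#' @return Tibble with `gene_id`, `mean_a`, `mean_b`, `fold_change`,
#'   `direction`. A zero denominator yields `Inf` (flagged for the caller).
#' @export
fold_change <- function(expr, samples_a, samples_b) {
  if (expr_scale(expr) != "linear") abort("fold_change() requires a linear matrix")
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(samples_a, samples_b)) > 0) {
    abort("groups must be disjoint")
  }
  m <- expr_matrix(expr)
  mean_a <- unname(rowMeans(m[, samples_a, drop = FALSE]))
  mean_b <- unname(rowMeans(m[, samples_b, drop = FALSE]))
  fc <- mean_a / mean_b
  tibble::tibble(
    gene_id = expr$gene_id,
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fc,
    direction = dplyr::if_else(fc > 1, "induced", "repressed")
  )
}
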