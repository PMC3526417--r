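#' Centered correlation distance
#'
#' `d = 1 - Pearson(a, b)`, ranging over \[0, 2\].
#'
#' @param a,b Equal-length numeric profiles (length >= 3, non-constant).
#' @return Scalar dissimilarity.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("profiles must have equal length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("correlation distance is undefined for a constant profile")
  }
  1 - cor(a, b)
}

# full pairwise centered-correlation dissimilarity matrix
correlation_dist_matrix <- function(m) {
  if (any(apply(m, 1, sd) == 0)) {
    abort("correlation distance is undefined for a constant profile")
  }
  d <- 1 - cor(t(m))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Merges the closest pair of clusters under the unweighted-average rule: the
#' distance between two clusters is the mean of all cross-pair leaf
#' distances. Ties in the minimum distance are broken by the smallest
#' (i, j) index pair, making the tree deterministic. The default
#' dissimilarity is the centered correlation distance on the supplied
#' profiles (gene-wise median-centered log2 expression values, in the
#' heat-map convention).
#'
#' @param profiles Numeric matrix (rows = items, with rownames) or a tibble
#'   whose first column is an id and remaining columns numeric.
#' @param dist_matrix Optional precomputed symmetric dissimilarity matrix;
#'   when given, `profiles` may be omitted.
#' @return An object of class `upgma_tree` with `merge`, `height`, `labels`,
#'   `order` in [stats::hclust()] conventions.
#' @export
#' @examples
#' m <- matrix(rnorm(30), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' tree <- agglomerate_average(m)
#' cut_k(tree, 2)
agglomerate_average <- function(profiles = NULL, dist_matrix = NULL) {
  if (is.null(dist_matrix)) {
    if (is.data.frame(profiles)) {
      m <- as.matrix(profiles[-1])
      rownames(m) <- profiles[[1]]
    } else {
      m <- as.matrix(profiles)
    }
    if (nrow(m) < 2) abort("need at least 2 profiles")
    d <- correlation_dist_matrix(m)
    labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  } else {
    d <- as.matrix(dist_matrix)
    if (nrow(d) < 2) abort("need at least 2 profiles")
    labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  }
  n <- nrow(d)
  diag(d) <- Inf
  code <- -seq_len(n)      # hclust convention: negative = leaf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    mn <- min(d[active, active])
    idx <- which(d == mn, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2] & active[idx[, 1]] & active[idx[, 2]], ,
               drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    merge[step, ] <- c(code[i], code[j])
    height[step] <- mn
    # unweighted average update onto slot i
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others) > 0) {
      d_new <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- d_new
      d[others, i] <- d_new
    }
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
    d[i, i] <- Inf
    size[i] <- size[i] + size[j]
    code[i] <- step
  }

  structure(
    list(merge = merge, height = height, labels = labels,
         order = tree_leaf_order(merge), method = "average",
         dist.method = "correlation"),
    class = "upgma_tree"
  )
}

# left-to-right leaf order from the merge matrix
tree_leaf_order <- function(merge) {
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(merge[code, 1]), expand(merge[code, 2]))
  }
  expand(nrow(merge))
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$method, dist.method = x$dist.method,
         call = match.call()),
    class = "hclust"
  )
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree>", length(x$labels), "leaves,", length(x$height),
      "merges, max height", format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.upgma_tree <- function(x, ...) {
  tibble::tibble(merge = seq_along(x$height),
                 left = x$merge[, 1], right = x$merge[, 2],
                 height = x$height)
}

#' @export
glance.upgma_tree <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels),
                 max_height = max(x$height),
                 monotone = !is.unsorted(x$height))
}

#' Cut a tree into k clusters
#'
#' Removes the k-1 highest merges.
#'
#' @param tree An `upgma_tree`.
#' @param k Number of clusters, 1..n.
#' @return Tibble with `label` and `cluster`.
#' @export
cut_k <- function(tree, k) {
  if (k < 1 || k > length(tree$labels)) abort("k must be in 1..n")
  cl <- cutree(as.hclust(tree), k = k)
  tibble::tibble(label = tree$labels, cluster = unname(cl))
}

#' Per-gene median centering of a log2 matrix
#'
#' The heat-map normalization convention: each gene's log2 profile is shifted
#' by its median.
#'
#' @param m Numeric matrix (genes x samples).
#' @return Centered matrix.
#' @export
median_center <- function(m) {
  sweep(m, 1, apply(m, 1, median), `-`)
}

#' Replicate-mean log2 profile matrix
#'
#' One column per genotype x condition cell (control first, then the cold
#' timepoints in order; recurrent parent before introgression line), each
#' entry the mean over replicates of log2 intensities.
#'
#' @param expr Linear-scale expression tibble.
#' @param design Design tibble.
#' @param pseudocount Linear pseudocount for the log2 transform.
#' @return Numeric matrix with gene rownames and `genotype_time` colnames.
#' @export
profile_matrix <- function(expr, design, pseudocount = 1) {
  lg <- expr_matrix(log2_view(expr, pseudocount))
  times <- c(0, sort(unique(design$time_h[design$condition == "cold"])))
  cols <- list()
  for (g in GENOTYPES) {
    for (t in times) {
      ids <- design$sample_id[design$genotype == g & design$time_h == t]
      cols[[paste0(g, "_", t, "h")]] <- rowMeans(lg[, ids, drop = FALSE])
    }
  }
  do.call(cbind, cols)
}
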