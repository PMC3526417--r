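#' Parameters for SAM two-class unpaired testing
#'
#' Bundles the permutation, fudge-factor and calling thresholds used by
#' [sam_permutation()] and [call_degs()]. A gene is called significant only
#' when its permutation p-value falls strictly below `p_threshold` *and* its
#' linear fold change exceeds `fc_threshold` (or falls below its reciprocal)
#' -- the conjunction of a p cutoff and a "more than 5-fold" gate.
#'
#' @param n_permutations Number of label assignments; when the number of
#'   distinct assignments (choose(n, n_a)) is at most this, all of them are
#'   enumerated ("exhaustive" mode; a 3v3 design gives exactly 20).
#' @param s0_mode `"percentile"` (of the per-gene pooled standard errors,
#'   default the median) or `"fixed"`.
#' @param s0_value Percentile in \[0, 100\] or the fixed s0 value.
#' @param seed Seed used only in sampled (non-exhaustive) mode.
#' @param fc_threshold Linear fold-change gate (strictly more than; default 5).
#' @param p_threshold Permutation p cutoff (strictly below; default 0.05).
#' @param null_mode How the permutation null is referenced: `"pooled"`
#'   (default) compares each gene's |d| against the permuted d-statistics of
#'   *all* genes, the standard SAM reference distribution, giving p a
#'   granularity of 1/(genes x assignments); `"per_gene"` compares only
#'   against the gene's own permuted values (granularity 1/assignments --
#'   with 3v3 the complement assignment always ties |d|, so per-gene p can
#'   never fall below 0.10 and is reported for diagnostics, not calling).
#' @param pseudocount Linear pseudocount for the log2 values d is computed on.
#' @return A list of class `sam_params`.
#' @export
sam_params <- function(n_permutations = 1000L,
                       s0_mode = c("percentile", "fixed"),
                       s0_value = 50,
                       seed = 1L,
                       fc_threshold = 5,
                       p_threshold = 0.05,
                       null_mode = c("pooled", "per_gene"),
                       pseudocount = 1) {
  s0_mode <- match.arg(s0_mode)
  null_mode <- match.arg(null_mode)
  if (fc_threshold <= 1) abort("fc_threshold must be > 1")
  if (p_threshold <= 0) abort("p_threshold must be positive")
  structure(
    list(n_permutations = as.integer(n_permutations), s0_mode = s0_mode,
         s0_value = s0_value, seed = as.integer(seed),
         fc_threshold = fc_threshold, p_threshold = p_threshold,
         null_mode = null_mode, pseudocount = pseudocount),
    class = "sam_params"
  )
}

#' SAM d-statistic for one gene
#'
#' `d = (mean(a) - mean(b)) / (s_i + s0)` where `s_i` is the two-sample
#' pooled standard error. With `s0 = 0`, d reduces to the equal-variance
#' two-sample t statistic. Inputs are log2-scale values.
#'
#' @param values_a,values_b Numeric vectors, at least 2 values each.
#' @param s0 Fudge factor added to the standard error.
#' @return Tibble with `d`, `mean_a`, `mean_b`, `pooled_se`.
#' @export
#' @examples
#' sam_d(c(5, 6, 7), c(1, 2, 3), s0 = 0.1)
sam_d <- function(values_a, values_b, s0 = 0) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  res <- d_stat(matrix(values_a, nrow = 1), matrix(values_b, nrow = 1), s0)
  tibble::tibble(d = res$d, mean_a = res$mean_a, mean_b = res$mean_b,
                 pooled_se = res$se)
}

# vectorised d over genes: Xa, Xb are genes x replicates matrices
d_stat <- function(Xa, Xb, s0) {
  na <- ncol(Xa)
  nb <- ncol(Xb)
  ma <- rowMeans(Xa)
  mb <- rowMeans(Xb)
  ssa <- rowSums((Xa - ma)^2)
  ssb <- rowSums((Xb - mb)^2)
  se <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(d = (ma - mb) / (se + s0), mean_a = ma, mean_b = mb, se = se)
}

#' Choose the SAM fudge factor s0
#'
#' @param pooled_se Non-empty vector of per-gene pooled standard errors.
#' @param mode `"percentile"` or `"fixed"`.
#' @param value Percentile in \[0, 100\] (default 50, the median) or the
#'   fixed value itself.
#' @return The s0 scalar.
#' @export
choose_s0 <- function(pooled_se, mode = c("percentile", "fixed"), value = 50) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(value)
  if (length(pooled_se) == 0) abort("empty standard-error vector")
  unname(quantile(pooled_se, value / 100, type = 7))
}

# All group-A column index sets, exhaustively when feasible else sampled.
# The first assignment is always the identity labelling.
enumerate_assignments <- function(n, n_a, n_permutations, seed) {
  total <- choose(n, n_a)
  if (total < 2) abort("fewer than 2 distinct label assignments possible")
  if (total <= n_permutations) {
    asn <- combn(n, n_a)
    # put the identity assignment (columns 1..n_a) first
    id_col <- which(apply(asn, 2, function(x) all(x == seq_len(n_a))))
    asn <- cbind(asn[, id_col], asn[, -id_col, drop = FALSE])
    list(assignments = asn, exhaustive = TRUE)
  } else {
    asn <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations - 1L),
             function(i) sort(sample.int(n, n_a)), integer(n_a))
    })
    list(assignments = cbind(seq_len(n_a), asn), exhaustive = FALSE)
  }
}

#' Permutation test on a two-class log2 matrix
#'
#' Computes the SAM d-statistic per gene, derives permutation p-values from
#' the chosen null reference (see [sam_params()]), and a SAM-style q-value:
#' at each gene's |d| cutoff, the median over permutations of the number of
#' permuted statistics exceeding the cutoff, divided by the observed number
#' of genes called at that cutoff, clipped to \[0, 1\] and monotonized.
#'
#' @param X Genes x samples numeric matrix of log2 values, with rownames.
#' @param labels Logical or two-level vector marking group A columns.
#' @param params A [sam_params()].
#' @return Tibble with `gene_id`, `d`, `pooled_se`, `p_value`, `q_value`,
#'   plus attributes `s0` and `n_assignments`.
#' @export
sam_permutation <- function(X, labels, params = sam_params()) {
  if (is.logical(labels)) {
    a_idx <- which(labels)
  } else {
    lev <- unique(labels)
    if (length(lev) != 2) abort("labels must have exactly two classes")
    a_idx <- which(labels == lev[1])
  }
  b_idx <- setdiff(seq_len(ncol(X)), a_idx)
  if (length(a_idx) < 2 || length(b_idx) < 2) {
    abort("each group needs at least 2 samples")
  }
  # reorder so group A occupies the leading columns (identity assignment)
  X <- X[, c(a_idx, b_idx), drop = FALSE]
  n_a <- length(a_idx)
  n <- ncol(X)

  se_obs <- d_stat(X[, seq_len(n_a), drop = FALSE],
                   X[, -seq_len(n_a), drop = FALSE], 0)$se
  s0 <- choose_s0(se_obs, params$s0_mode, params$s0_value)

  en <- enumerate_assignments(n, n_a, params$n_permutations, params$seed)
  asn <- en$assignments
  B <- ncol(asn)
  G <- nrow(X)
  D <- matrix(0, nrow = G, ncol = B)
  for (b in seq_len(B)) {
    ia <- asn[, b]
    D[, b] <- d_stat(X[, ia, drop = FALSE],
                     X[, -ia, drop = FALSE], s0)$d
  }
  d_obs <- D[, 1]
  absD <- abs(D)
  abs_obs <- abs(d_obs)

  if (params$null_mode == "per_gene") {
    p <- rowMeans(absD >= abs_obs)
  } else {
    pool <- sort(as.vector(absD))
    # exceedances counting ties: total minus strictly-smaller values
    p <- (length(pool) - findInterval(abs_obs, pool, left.open = TRUE)) /
      length(pool)
  }

  # SAM-style q: median false-call count over permutations at each |d| cutoff
  obs_sorted <- sort(abs_obs)
  n_called <- G - findInterval(abs_obs, obs_sorted, left.open = TRUE)
  false_counts <- matrix(0, nrow = G, ncol = B)
  for (b in seq_len(B)) {
    col_sorted <- sort(absD[, b])
    false_counts[, b] <- G - findInterval(abs_obs, col_sorted, left.open = TRUE)
  }
  q <- pmin(1, apply(false_counts, 1, median) / n_called)
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- rev(cummin(rev(q[ord])))

  out <- tibble::tibble(
    gene_id = rownames(X) %||% as.character(seq_len(G)),
    d = d_obs, pooled_se = se_obs, p_value = p, q_value = q
  )
  attr(out, "s0") <- s0
  attr(out, "n_assignments") <- B
  attr(out, "exhaustive") <- en$exhaustive
  out
}
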