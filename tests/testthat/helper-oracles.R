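# Independent brute-force oracles used across test files. Each recomputes
# its quantity from first principles, without touching the implementation
# path it checks.

# equal-variance two-sample t statistic
t_stat_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# naive O(n^3) UPGMA: recompute every cluster distance from scratch as the
# mean over all cross-pair leaf distances
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights[step] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# naive sliding-window motif search
scan_oracle <- function(seq, both_strands = TRUE) {
  words <- c("GCCGAC", "ACCGAC")
  strands <- c("+", "+")
  if (both_strands) {
    words <- c(words, "GTCGGC", "GTCGGT")
    strands <- c(strands, "-", "-")
  }
  out <- list()
  for (i in seq_len(nchar(seq) - 5)) {
    win <- substr(seq, i, i + 5)
    for (h in which(words == win)) {
      out[[length(out) + 1]] <- tibble::tibble(offset = i - 1L,
                                               strand = strands[h],
                                               word = words[h])
    }
  }
  dplyr::bind_rows(out)
}

# direct combinatorial sum for the upper hypergeometric tail
hyper_oracle <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# O(n^2) brute-force interval overlap
overlap_oracle <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    hit <- which(same & lo < hi)
    if (length(hit)) {
      out[[length(out) + 1]] <- tibble::tibble(
        name_a = a$name[i], name_b = b$name[hit], overlap = (hi - lo)[hit]
      )
    }
  }
  dplyr::bind_rows(out)
}
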