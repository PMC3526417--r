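#' Upper hypergeometric tail probability
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' from a population of `N` of which `K` carry the term, the probability of
#' seeing `k` or more carriers.
#'
#' @param k Observed carriers in the study set.
#' @param n Study-set size.
#' @param K Population carriers.
#' @param N Population size.
#' @return The tail probability (vectorised over its arguments).
#' @export
#' @examples
#' hypergeom_tail(3, 6, 5, 20)
hypergeom_tail <- function(k, n, K, N) {
  if (any(!(K <= N & n <= N & k >= 0 & k <= n & k <= K))) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of annotation terms in a gene set
#'
#' One-sided hypergeometric test of each term with at least one study-set
#' hit, against a flat term -> gene annotation (GO-slim style; any desired
#' true-path propagation must be pre-applied to the annotation). Raw p and
#' Benjamini-Hochberg adjusted p across the tested terms are both reported.
#'
#' @param study Character vector of study-set gene ids (must lie within
#'   `population`).
#' @param annotation Tibble with `term`, `description` and a `genes`
#'   list-column (as from [read_gmt()] or [simulate_annotation()]).
#' @param population Character vector of population gene ids; genes without
#'   any annotation still count in the population size.
#' @return Tibble sorted by p with `term`, `description`, `k`, `n`, `K`,
#'   `N`, `fraction` (= k/n), `p_value`, `p_adjusted`.
#' @export
enrich_terms <- function(study, annotation, population) {
  study <- unique(study)
  population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside) > 0) {
    abort(paste0("study gene(s) outside the population: ",
                 paste(head(outside, 3), collapse = ", ")))
  }
  n <- length(study)
  N <- length(population)
  res <- pmap(annotation[c("term", "description", "genes")],
              function(term, description, genes) {
                members <- intersect(genes, population)
                k <- length(intersect(study, members))
                if (k == 0) return(NULL)
                K <- length(members)
                tibble::tibble(term = term, description = description,
                               k = k, n = n, K = K, N = N,
                               fraction = k / n,
                               p_value = hypergeom_tail(k, n, K, N))
              })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    res <- tibble::tibble(term = character(0), description = character(0),
                          k = integer(0), n = integer(0), K = integer(0),
                          N = integer(0), fraction = numeric(0),
                          p_value = numeric(0), p_adjusted = numeric(0))
  } else {
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
    res <- dplyr::arrange(res, .data$p_value)
  }
  class(res) <- c("cold_enrich", class(res))
  res
}
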