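#' Fold-change / p-value scatter of DEG calls
#'
#' @param object A `sam_deg` tibble from [call_degs()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 permutation p with the
#'   calling gates drawn as dashed lines.
#' @export
autoplot.sam_deg <- function(object, ...) {
  params <- attr(object, "params") %||% sam_params()
  df <- tibble::as_tibble(object)
  df$log2_fc <- log2(df$fold_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(params$fc_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(params$p_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 permutation p",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Time-course expression profiles for selected genes
#'
#' Replicate-mean log2 intensity against time (pooled control drawn at 0 h),
#' one line per gene, facetted by genotype.
#'
#' @param expr Linear-scale expression tibble.
#' @param design Design tibble.
#' @param genes Character vector of gene ids.
#' @return A ggplot.
#' @export
plot_profiles <- function(expr, design, genes) {
  prof <- profile_matrix(expr, design)[genes, , drop = FALSE]
  df <- tibble::as_tibble(prof, rownames = "gene_id")
  df <- tidyr::pivot_longer(df, -"gene_id", names_to = "cell",
                            values_to = "log2_intensity")
  df <- tidyr::separate_wider_regex(
    df, "cell", c(genotype = ".*", "_", time = "[0-9]+", "h")
  )
  df$time_h <- as.numeric(df$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                   y = .data$log2_intensity,
                                   group = .data$gene_id,
                                   colour = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "time under cold (h, control at 0)",
                  y = "mean log2 intensity") +
    ggplot2::theme_minimal()
}

#' Dendrogram of an average-linkage tree
#'
#' @param object An `upgma_tree`.
#' @param ... Unused.
#' @return A ggplot drawing the merge structure.
#' @export
autoplot.upgma_tree <- function(object, ...) {
  n <- length(object$labels)
  x_leaf <- setNames(seq_len(n), object$order)
  xpos <- numeric(n - 1)
  ypos <- object$height
  segs <- list()
  node_x <- function(code) {
    if (code < 0) x_leaf[[as.character(-code)]] else xpos[code]
  }
  node_y <- function(code) if (code < 0) 0 else ypos[code]
  for (m in seq_len(n - 1)) {
    xl <- node_x(object$merge[m, 1]); yl <- node_y(object$merge[m, 1])
    xr <- node_x(object$merge[m, 2]); yr <- node_y(object$merge[m, 2])
    xpos[m] <- (xl + xr) / 2
    segs[[m]] <- tibble::tibble(
      x = c(xl, xl, xr), xend = c(xl, xr, xr),
      y = c(yl, ypos[m], ypos[m]), yend = c(ypos[m], ypos[m], yr)
    )
  }
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[object$order]) +
    ggplot2::labs(x = NULL, y = "merge height (1 - r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Bar chart of enriched terms
#'
#' @param object A `cold_enrich` tibble from [enrich_terms()].
#' @param top Number of terms shown (default 15).
#' @param ... Unused.
#' @return A ggplot of -log10 adjusted p for the top terms.
#' @export
autoplot.cold_enrich <- function(object, top = 15, ...) {
  df <- head(tibble::as_tibble(object), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}
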