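#' Contrast specifications
#'
#' Two families of contrasts are analysed: within a genotype, each cold
#' timepoint against that genotype's pooled control (`cold_contrast()`); and
#' between genotypes at the control or at a given cold timepoint
#' (`genotype_contrast()`, introgression line vs recurrent parent).
#'
#' @param genotype `"recurrent"` or `"introgression"`.
#' @param time_h Timepoint in hours; for `genotype_contrast()`, 0 means the
#'   pooled control.
#' @return A list of class `deg_contrast`.
#' @export
cold_contrast <- function(genotype, time_h) {
  if (!genotype %in% GENOTYPES) abort(paste0("unknown genotype '", genotype, "'"))
  structure(list(type = "cold", genotype = genotype, time_h = time_h,
                 label = paste0(genotype, "_cold_", time_h, "h_vs_control")),
            class = "deg_contrast")
}

#' @rdname cold_contrast
#' @export
genotype_contrast <- function(time_h) {
  lab <- if (time_h == 0) "il_vs_recurrent_control" else
    paste0("il_vs_recurrent_", time_h, "h")
  structure(list(type = "genotype", genotype = NA_character_, time_h = time_h,
                 label = lab),
            class = "deg_contrast")
}

# resolve a contrast to the two sample-id groups (A first)
contrast_groups <- function(contrast, design) {
  pick <- function(genotype, condition, time_h) {
    design$sample_id[design$genotype == genotype &
                       design$condition == condition &
                       design$time_h == time_h]
  }
  if (contrast$type == "cold") {
    a <- pick(contrast$genotype, "cold", contrast$time_h)
    b <- pick(contrast$genotype, "control", 0)
  } else if (contrast$type == "genotype") {
    cond <- if (contrast$time_h == 0) "control" else "cold"
    a <- pick("introgression", cond, contrast$time_h)
    b <- pick("recurrent", cond, contrast$time_h)
  } else {
    abort(paste0("unknown contrast type '", contrast$type, "'"))
  }
  if (length(a) == 0 || length(b) == 0) {
    abort(paste0("contrast '", contrast$label,
                 "' is not resolvable from the design"))
  }
  list(a = a, b = b)
}

#' Every contrast implied by a design
#'
#' One cold-vs-control contrast per genotype and timepoint, plus one
#' between-genotype contrast at the control and at each timepoint.
#'
#' @param design Design tibble.
#' @return List of [cold_contrast()] / [genotype_contrast()] objects.
#' @export
all_contrasts <- function(design) {
  times <- sort(unique(design$time_h[design$condition == "cold"]))
  c(
    unlist(lapply(GENOTYPES, function(g) {
      lapply(times, function(t) cold_contrast(g, t))
    }), recursive = FALSE),
    lapply(c(0, times), genotype_contrast)
  )
}

#' Call differentially expressed genes for one contrast
#'
#' The d-statistic and permutation p come from log2-normalized values
#' ([sam_permutation()]); the fold change is the ratio of linear replicate
#' means. A gene is significant when `p < p_threshold` and its fold change is
#' more than `fc_threshold` (induced) or less than `1/fc_threshold`
#' (repressed).
#'
#' @param expr Normalized linear-scale expression tibble.
#' @param design Design tibble describing `expr`'s sample columns.
#' @param contrast A [cold_contrast()] or [genotype_contrast()].
#' @param params A [sam_params()].
#' @param expressed Optional character vector restricting testing to these
#'   gene ids (from [detect_expressed()]).
#' @return A `sam_deg` tibble: one row per tested gene with contrast labels,
#'   linear means, `pooled_se`, `d_statistic`, `fold_change`, `p_value`,
#'   `q_value`, `direction` and `significant`.
#' @export
call_degs <- function(expr, design, contrast, params = sam_params(),
                      expressed = NULL) {
  stopifnot(inherits(contrast, "deg_contrast"))
  validate_design(design, expr)
  if (!is.null(expressed)) {
    expr <- expr[expr$gene_id %in% expressed, , drop = FALSE]
    attr(expr, "scale") <- "linear"
  }
  grp <- contrast_groups(contrast, design)
  lg <- log2_view(expr, params$pseudocount)
  X <- expr_matrix(lg)[, c(grp$a, grp$b), drop = FALSE]
  sam <- sam_permutation(X, c(rep(TRUE, length(grp$a)),
                              rep(FALSE, length(grp$b))), params)
  fc <- fold_change(expr, grp$a, grp$b)

  ct <- contrast
  out <- tibble::tibble(
    gene_id = expr$gene_id,
    contrast = ct$label,
    contrast_type = ct$type,
    genotype = ct$genotype,
    time_h = ct$time_h,
    mean_a = fc$mean_a, mean_b = fc$mean_b,
    pooled_se = sam$pooled_se,
    d_statistic = sam$d,
    fold_change = fc$fold_change,
    p_value = sam$p_value,
    q_value = sam$q_value,
    direction = fc$direction,
    significant = sam$p_value < params$p_threshold &
      (fc$fold_change > params$fc_threshold |
         fc$fold_change < 1 / params$fc_threshold)
  )
  class(out) <- c("sam_deg", class(out))
  attr(out, "params") <- params
  attr(out, "s0") <- attr(sam, "s0")
  attr(out, "n_assignments") <- attr(sam, "n_assignments")
  out
}

#' Call DEGs for every contrast in the design
#'
#' @inheritParams call_degs
#' @return One long `sam_deg` tibble over all contrasts.
#' @export
call_degs_all <- function(expr, design, params = sam_params(),
                          expressed = NULL) {
  res <- lapply(all_contrasts(design), function(ct) {
    call_degs(expr, design, ct, params, expressed)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("sam_deg", class(out))
  attr(out, "params") <- params
  out
}

#' @export
glance.sam_deg <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$contrast),
    n_tested = dplyr::n(),
    n_significant = sum(.data$significant),
    n_induced = sum(.data$significant & .data$direction == "induced"),
    n_repressed = sum(.data$significant & .data$direction == "repressed"),
    .groups = "drop"
  )
}
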