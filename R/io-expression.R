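#' Read and write expression matrices with their sample design
#'
#' The on-disk form is a pair of UTF-8 tab-separated files: the matrix with a
#' `gene_id` first column and one column per sample, and a design table with
#' one row per sample (`sample_id`, `genotype`, `condition`, `time_h`,
#' `replicate`). The pooled control is represented as `condition = "control"`,
#' `time_h = 0`.
#'
#' @param path Matrix TSV path.
#' @param design_path Design TSV path.
#' @param scale Scale flag recorded on the returned tibble, `"linear"`
#'   (default) or `"log2"`.
#' @return `read_expression()`: a tibble (first column `gene_id`) with a
#'   `scale` attribute, plus the design as attribute `"design"` is *not*
#'   attached -- use [read_design()].
#' @export
read_expression <- function(path, design_path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "gene_id") {
    abort("expression format error: first column must be 'gene_id'")
  }
  if (anyDuplicated(raw$gene_id)) {
    dup <- raw$gene_id[duplicated(raw$gene_id)][1]
    abort(paste0("expression format error: duplicate gene id '", dup, "'"))
  }
  design <- read_design(design_path)
  missing <- setdiff(names(raw)[-1], design$sample_id)
  if (length(missing) > 0) {
    abort(paste0("design does not describe sample column(s): ",
                 paste(missing, collapse = ", ")))
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort(paste0("expression format error: non-numeric value '",
                   vals[[j]][bad[1]], "' at gene '", raw$gene_id[bad[1]],
                   "', sample '", names(vals)[j], "'"))
    }
    if (scale == "linear" && any(num < 0)) {
      abort(paste0("expression format error: negative intensity in sample '",
                   names(vals)[j], "'"))
    }
    vals[[j]] <- num
  }
  out <- dplyr::bind_cols(raw[1], vals)
  attr(out, "scale") <- scale
  out
}

#' @rdname read_expression
#' @param expr Expression tibble (first column `gene_id`).
#' @param design Design tibble.
#' @export
write_expression <- function(expr, design, path, design_path) {
  validate_design(design, expr)
  readr::write_tsv(expr, path, progress = FALSE)
  readr::write_tsv(design, design_path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_design <- function(design_path) {
  design <- readr::read_tsv(
    design_path,
    col_types = readr::cols(
      sample_id = readr::col_character(), genotype = readr::col_character(),
      condition = readr::col_character(), time_h = readr::col_double(),
      replicate = readr::col_integer()
    ), progress = FALSE
  )
  validate_design(design)
  design
}

validate_design <- function(design, expr = NULL) {
  need <- c("sample_id", "genotype", "condition", "time_h", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    abort(paste0("design is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(design$genotype %in% GENOTYPES)) {
    abort("design error: genotype must be 'recurrent' or 'introgression'")
  }
  if (!all(design$condition %in% c("control", "cold"))) {
    abort("design error: condition must be 'control' or 'cold'")
  }
  if (any((design$condition == "control") != (design$time_h == 0))) {
    abort("design error: condition 'control' if and only if time_h = 0")
  }
  key <- paste(design$genotype, design$condition, design$time_h, design$replicate)
  if (anyDuplicated(key)) {
    abort("design error: duplicate (genotype, condition, time_h, replicate)")
  }
  if (!is.null(expr)) {
    miss <- setdiff(names(expr)[-1], design$sample_id)
    if (length(miss) > 0) {
      abort(paste0("design does not describe sample column(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  invisible(design)
}

# genes x samples numeric matrix view of an expression tibble
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  m
}

expr_scale <- function(expr) attr(expr, "scale") %||% "linear"

# rebuild an expression tibble from a matrix, keeping the scale flag
expr_from_matrix <- function(m, scale) {
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m))
  attr(out, "scale") <- scale
  out
}
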