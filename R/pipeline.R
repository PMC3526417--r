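#' Run the whole comparative cold-stress analysis from one configuration
#'
#' Orchestrates every stage -- simulate (or load), normalize, presence
#' calling, SAM DEG calling over all contrasts, temporal set classification,
#' pattern clustering, DRE regulon construction, GO enrichment, and
#' segment/QTL co-localization -- writing a deterministic output directory
#' plus a machine-readable manifest (seed, parameters, package version, md5
#' of every output) and a log with per-stage timings. Any stage error aborts
#' with the stage name and cause.
#'
#' @param config A configuration list or path to a YAML file. With a
#'   `simulate:` block (see [sim_config()] for its keys) the inputs are
#'   generated; otherwise an `inputs:` block must name `expression` and
#'   `design` TSV paths (and optionally `promoters` FASTA, `genes`,
#'   `segments`, `qtls` BED and `gmt` paths and `regulon: drivers:`).
#'   Optional stage sections: `detect: threshold`, `deg:` (keys of
#'   [sam_params()]), `cluster: k`, `coloc: flank`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_cold_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  timings <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    writeLines(sprintf("stage %-12s %8.2fs", name, dt), log_con)
    res
  }
  outputs <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(x, p, progress = FALSE)
    outputs <<- c(outputs, name)
    invisible(p)
  }

  # ---- inputs ----
  sim <- NULL
  ann <- NULL
  prom <- NULL
  if (!is.null(config$simulate)) {
    dat <- run_stage("simulate", function() {
      cfg <- do.call(sim_config, config$simulate)
      sim <- simulate_dataset(cfg)
      list(cfg = cfg, sim = sim,
           prom = simulate_promoters(sim$truth, cfg),
           ann = simulate_annotation(sim$truth, cfg))
    })
    expr <- dat$sim$expression
    design <- dat$sim$design
    sim <- dat$sim
    prom <- dat$prom$promoters
    ann <- dat$ann
    drivers <- setNames(sim$truth$gene_id[!is.na(sim$truth$driver)],
                        sim$truth$driver[!is.na(sim$truth$driver)])
    seed_used <- config$simulate$seed
  } else {
    if (is.null(config$inputs$expression)) abort("config missing key 'inputs.expression'")
    if (is.null(config$inputs$design)) abort("config missing key 'inputs.design'")
    expr <- run_stage("load", function() {
      read_expression(config$inputs$expression, config$inputs$design)
    })
    design <- read_design(config$inputs$design)
    if (!is.null(config$inputs$promoters)) prom <- read_fasta(config$inputs$promoters)
    ann <- list(
      genes = if (!is.null(config$inputs$genes)) read_bed(config$inputs$genes, "gene"),
      segments = if (!is.null(config$inputs$segments)) read_bed(config$inputs$segments, "segment"),
      qtls = if (!is.null(config$inputs$qtls)) read_bed(config$inputs$qtls, "qtl"),
      go = if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt)
    )
    drivers <- unlist(config$regulon$drivers)
    seed_used <- config$deg$seed %||% 1L
  }

  # ---- preprocess ----
  norm <- run_stage("normalize", function() normalize_arrays(expr))
  save_tsv(norm, "norm.tsv")
  save_tsv(design, "design.tsv")
  threshold <- config$detect$threshold %||% 100
  det <- run_stage("detect", function() detect_expressed(norm, threshold))
  save_tsv(tibble::tibble(gene_id = det$expressed), "expressed.tsv")

  # ---- DEG calling ----
  params <- do.call(sam_params, config$deg %||% list())
  degs <- run_stage("deg", function() {
    call_degs_all(norm, design, params, det$expressed)
  })
  save_tsv(tibble::as_tibble(degs), "degs/all_contrasts.tsv")
  save_tsv(glance(degs), "summary_contrasts.tsv")

  # ---- temporal sets ----
  sets <- run_stage("classify", function() {
    part <- classify_common_specific(degs)
    list(partition = part,
         continuous = continuous_response(degs),
         constitutive = constitutive_degs(degs),
         venn = venn_counts(degs))
  })
  save_tsv(sets$partition$per_phase, "sets/per_phase.tsv")
  save_tsv(sets$partition$totals, "sets/totals.tsv")
  save_tsv(sets$continuous, "sets/continuous.tsv")
  save_tsv(sets$constitutive, "sets/constitutive.tsv")
  save_tsv(sets$venn, "sets/venn_counts.tsv")
  save_tsv(glance(sets$partition), "summary_sets.tsv")

  # ---- clustering of all DEGs ----
  deg_ids <- sort(unique(c(
    tibble::as_tibble(degs)$gene_id[degs$significant]
  )))
  clusters <- run_stage("cluster", function() {
    if (length(deg_ids) < 2) return(NULL)
    prof <- median_center(profile_matrix(norm, design)[deg_ids, , drop = FALSE])
    tree <- agglomerate_average(prof)
    cut_k(tree, min(config$cluster$k %||% 6, length(deg_ids)))
  })
  if (!is.null(clusters)) save_tsv(clusters, "clusters.tsv")

  # ---- regulon ----
  regulon <- NULL
  if (!is.null(prom) && length(drivers) == 3) {
    regulon <- run_stage("regulon", function() {
      common_ind <- sets$partition$totals$gene_id[
        sets$partition$totals$set == "common" &
          sets$partition$totals$direction == "induced"]
      p <- prom
      if (!"gene_id" %in% names(p)) p <- dplyr::rename(p, gene_id = "name")
      hits <- scan_dre(p)
      list(hits = hits,
           assign = assign_regulons(common_ind, hits, norm, design, drivers))
    })
    save_tsv(regulon$hits, "dre_hits.tsv")
    save_tsv(regulon$assign, "regulon.tsv")
  }

  # ---- GO enrichment of genotype-specific DEGs ----
  enrichment <- NULL
  if (!is.null(ann$go)) {
    enrichment <- run_stage("enrich", function() {
      study <- unique(sets$partition$totals$gene_id[
        sets$partition$totals$set != "common"])
      enrich_terms(intersect(study, det$expressed), ann$go, det$expressed)
    })
    save_tsv(enrichment, "enrichment.tsv")
  }

  # ---- co-localization ----
  coloc <- NULL
  if (!is.null(ann$genes) && !is.null(ann$segments)) {
    coloc <- run_stage("colocalize", function() {
      deg_sets <- dplyr::bind_rows(
        sets$partition$totals[c("gene_id", "set")],
        sets$constitutive[c("set", "gene_id")]
      )
      colocalization_report(deg_sets, ann$genes, ann$segments,
                            ann$qtls %||% ann$segments[0, ],
                            flank = config$coloc$flank %||% 0)
    })
    save_tsv(tidy(coloc), "colocalization.tsv")
    save_tsv(coloc$in_segment, "colocalization_genes.tsv")
    save_tsv(tibble::tibble(gene_id = coloc$unlinked), "colocalization_unlinked.tsv")
  }

  # ---- manifest ----
  manifest <- list(
    package = "introcold",
    version = as.character(utils::packageVersion("introcold")),
    seed = seed_used,
    parameters = config,
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(outputs))) |>
                        setNames(sort(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  writeLines(sprintf("total %16.2fs", sum(unlist(timings))), log_con)

  invisible(list(norm = norm, design = design, expressed = det$expressed,
                 degs = degs, sets = sets, clusters = clusters,
                 regulon = regulon, enrichment = enrichment, coloc = coloc,
                 manifest = manifest))
}
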