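#' Map a cold-stress timepoint to its response phase
#'
#' Early response is phase I (2 and 6 h), middle response phase II (12 h),
#' late response phase III (24 and 48 h).
#'
#' @param time_h Vector of timepoints in hours.
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' assign_phase(c(2, 12, 48))
assign_phase <- function(time_h) {
  map <- c(`2` = "I", `6` = "I", `12` = "II", `24` = "III", `48` = "III")
  key <- as.character(time_h)
  if (!all(key %in% names(map))) {
    abort("time must be one of 2, 6, 12, 24, 48 h")
  }
  unname(map[key])
}

# significant within-genotype cold calls, one row per (gene, genotype, time, direction)
cold_sig <- function(degs) {
  sig <- dplyr::filter(tibble::as_tibble(degs),
                       .data$contrast_type == "cold", .data$significant)
  sig$phase <- assign_phase(sig$time_h)
  sig
}

check_universes <- function(degs) {
  u <- split(degs$gene_id, degs$contrast)
  first <- sort(u[[1]])
  same <- vapply(u, function(x) identical(sort(x), first), logical(1))
  if (!all(same)) abort("DEG tables come from mismatched gene universes")
  invisible(first)
}

#' Partition cold-responsive genes into common and genotype-specific sets
#'
#' Per direction, a gene significant in both genotypes at one or more
#' timepoints is *common*; a gene significant in only one genotype (the other
#' never significant in that direction at any stage) is *genotype-specific*.
#' These global sets are then intersected with per-phase significance to give
#' the phase x direction tables; the totals are the redundancy-removed global
#' sets. Genes induced in one genotype but repressed in the other end up in
#' both directions' specific ledgers and are flagged as conflicts.
#'
#' @param degs Long `sam_deg` tibble over (at least) all within-genotype cold
#'   contrasts, from [call_degs_all()].
#' @param same_timepoint If `TRUE`, per-phase common membership requires
#'   co-significance at the same timepoint rather than anywhere in the phase.
#' @return A list of class `gene_set_partition`: `per_phase` (tibble `phase`,
#'   `direction`, `set`, `gene_id`), `totals` (tibble `direction`, `set`,
#'   `gene_id`), `conflicts` (gene ids with opposite directions in the two
#'   genotypes).
#' @export
classify_common_specific <- function(degs, same_timepoint = FALSE) {
  check_universes(degs)
  sig <- cold_sig(degs)
  phases <- c("I", "II", "III")

  per_phase <- list()
  totals <- list()
  for (dir in c("induced", "repressed")) {
    s <- dplyr::filter(sig, .data$direction == dir)
    in_rec <- unique(s$gene_id[s$genotype == "recurrent"])
    in_il <- unique(s$gene_id[s$genotype == "introgression"])
    common <- intersect(in_rec, in_il)
    rec_only <- setdiff(in_rec, in_il)
    il_only <- setdiff(in_il, in_rec)
    totals[[dir]] <- tibble::tibble(
      direction = dir,
      set = rep(c("common", "recurrent_specific", "il_specific"),
                c(length(common), length(rec_only), length(il_only))),
      gene_id = c(common, rec_only, il_only)
    )
    for (ph in phases) {
      sp <- dplyr::filter(s, .data$phase == ph)
      if (same_timepoint) {
        both_t <- dplyr::inner_join(
          dplyr::distinct(sp[sp$genotype == "recurrent", c("gene_id", "time_h")]),
          dplyr::distinct(sp[sp$genotype == "introgression", c("gene_id", "time_h")]),
          by = c("gene_id", "time_h")
        )
        common_ph <- intersect(common, unique(both_t$gene_id))
      } else {
        common_ph <- intersect(common, unique(sp$gene_id))
      }
      rec_ph <- intersect(rec_only, unique(sp$gene_id[sp$genotype == "recurrent"]))
      il_ph <- intersect(il_only, unique(sp$gene_id[sp$genotype == "introgression"]))
      per_phase[[paste(dir, ph)]] <- tibble::tibble(
        phase = ph, direction = dir,
        set = rep(c("common", "recurrent_specific", "il_specific"),
                  c(length(common_ph), length(rec_ph), length(il_ph))),
        gene_id = c(common_ph, rec_ph, il_ph)
      )
    }
  }
  totals <- dplyr::bind_rows(totals)
  spec <- function(dir, set) {
    totals$gene_id[totals$direction == dir & totals$set == set]
  }
  conflicts <- union(
    intersect(spec("induced", "recurrent_specific"), spec("repressed", "il_specific")),
    intersect(spec("induced", "il_specific"), spec("repressed", "recurrent_specific"))
  )
  structure(
    list(per_phase = dplyr::bind_rows(per_phase),
         totals = totals,
         conflicts = conflicts),
    class = "gene_set_partition"
  )
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("<gene_set_partition>\n")
  print(dplyr::count(x$totals, .data$direction, .data$set))
  if (length(x$conflicts)) {
    cat("direction conflicts:", length(x$conflicts), "gene(s)\n")
  }
  invisible(x)
}

#' @export
tidy.gene_set_partition <- function(x, ...) x$per_phase

#' @export
glance.gene_set_partition <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::count(x$totals, .data$set, .data$direction),
    names_from = "direction", values_from = "n", values_fill = 0L
  )
}

#' Continuously cold-regulated genes
#'
#' Genes significantly induced (or repressed) in a genotype at one or more
#' timepoints of *every* phase (I, II and III) over the whole time course.
#'
#' @inheritParams classify_common_specific
#' @return Tibble with `genotype`, `direction`, `gene_id`.
#' @export
continuous_response <- function(degs) {
  sig <- cold_sig(degs)
  hits <- dplyr::distinct(sig, .data$genotype, .data$direction,
                          .data$gene_id, .data$phase)
  cover <- dplyr::summarise(
    dplyr::group_by(hits, .data$genotype, .data$direction, .data$gene_id),
    n_phases = dplyr::n_distinct(.data$phase), .groups = "drop"
  )
  dplyr::select(dplyr::filter(cover, .data$n_phases == 3L),
                "genotype", "direction", "gene_id")
}

#' Venn region counts of cold-regulated genes across phases
#'
#' For each genotype and direction, counts genes by the exact combination of
#' phases in which they are significant (the seven Venn regions over phases
#' I, II, III).
#'
#' @inheritParams classify_common_specific
#' @return Tibble with `genotype`, `direction`, `phases` (e.g. `"I+III"`),
#'   `n`.
#' @export
venn_counts <- function(degs) {
  sig <- cold_sig(degs)
  hits <- dplyr::distinct(sig, .data$genotype, .data$direction,
                          .data$gene_id, .data$phase)
  combo <- dplyr::summarise(
    dplyr::group_by(hits, .data$genotype, .data$direction, .data$gene_id),
    phases = paste(sort(unique(.data$phase)), collapse = "+"),
    .groups = "drop"
  )
  dplyr::count(combo, .data$genotype, .data$direction, .data$phases)
}

#' Constitutive between-genotype DEGs
#'
#' Genes expressed at significantly different levels between the two
#' genotypes under control conditions and *not* responsive to cold in either
#' genotype (never significant in any within-genotype cold contrast).
#'
#' @param degs Long `sam_deg` tibble containing both the within-genotype cold
#'   contrasts and the between-genotype contrasts (from [call_degs_all()]).
#' @return Tibble with `set` (`"constitutive_up_il"` / `"constitutive_down_il"`)
#'   and `gene_id`.
#' @export
constitutive_degs <- function(degs) {
  tbl <- tibble::as_tibble(degs)
  ctrl <- dplyr::filter(tbl, .data$contrast_type == "genotype",
                        .data$time_h == 0, .data$significant)
  if (nrow(dplyr::filter(tbl, .data$contrast_type == "genotype")) == 0) {
    abort("no between-genotype contrasts in the DEG table")
  }
  cold_responsive <- unique(cold_sig(tbl)$gene_id)
  keep <- !ctrl$gene_id %in% cold_responsive
  tibble::tibble(
    set = dplyr::if_else(ctrl$direction[keep] == "induced",
                         "constitutive_up_il", "constitutive_down_il"),
    gene_id = ctrl$gene_id[keep]
  )
}
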