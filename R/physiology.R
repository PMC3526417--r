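#' Electrolyte-leakage membrane injury
#'
#' `injury = (L_t - L_c) / (100 - L_c) * 100`, where `L_t` and `L_c` are the
#' percent conductivities of the treated and control samples. Negative
#' injuries (treated below control) are reported as-is and flagged rather
#' than clipped.
#'
#' @param l_t,l_c Percent conductivities in \[0, 100\]; `l_c` must be < 100.
#' @return Numeric vector of percent injury.
#' @export
#' @examples
#' percent_injury(55, 10) # 50
percent_injury <- function(l_t, l_c) {
  if (any(l_c >= 100) || any(l_c < 0)) {
    abort("control conductivity must satisfy 0 <= L_c < 100")
  }
  if (any(l_t < 0) || any(l_t > 100)) {
    abort("treated conductivity must lie in [0, 100]")
  }
  (l_t - l_c) / (100 - l_c) * 100
}

#' Per-replicate injury with group summaries
#'
#' @param data Tibble with columns `group` (or `condition`), `l_t`, `l_c`.
#' @return List with `replicates` (input plus `injury` and a `negative`
#'   flag) and `summary` (per-group mean and sd).
#' @export
injury_summary <- function(data) {
  grp <- if ("group" %in% names(data)) "group" else "condition"
  reps <- dplyr::mutate(tibble::as_tibble(data),
                        injury = percent_injury(.data$l_t, .data$l_c),
                        negative = .data$injury < 0)
  summary <- dplyr::summarise(
    dplyr::group_by(reps, .data[[grp]]),
    mean_injury = mean(.data$injury),
    sd_injury = sd(.data$injury),
    n = dplyr::n(), .groups = "drop"
  )
  list(replicates = reps, summary = summary)
}
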