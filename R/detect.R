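# Diagnostic-ion detection in PRM MS2 scans.

#' Legal cleavage coordinates for a species of unknown positions
#'
#' The grid of (p, u) pairs any regioisomer of the species could
#' produce: on a chain with c carbons and d double bonds the (u+1)-th
#' C=C from the methyl end can sit anywhere in
#' `[min_n + spacing*u, c - 2 - spacing*(d-1-u)]`. Sum compositions use
#' a single pseudo-chain of the summed counts, bounded by the longest
#' chain the composition admits (co-chains of at least 2 carbons).
#'
#' @param annotation Species (string or `lipid_annotation`).
#' @param rules Position bounds, see [position_rules()].
#' @return Tibble `p`, `u` (distinct, sorted).
#' @export
legal_events <- function(annotation, rules = position_rules()) {
  ann <- .as_lipid(annotation)
  chains <- .candidate_chains(ann)
  rows <- purrr::map_dfr(chains, function(ch) {
    d <- ch$double_bonds
    if (d == 0) return(NULL)
    purrr::map_dfr(seq_len(d) - 1L, function(u) {
      lo <- rules$min_n + rules$min_spacing * u
      hi <- ch$carbons - 2L - rules$min_spacing * (d - 1L - u)
      if (lo > hi) return(NULL)
      tibble::tibble(p = seq.int(lo, hi), u = u)
    })
  })
  dplyr::distinct(rows) |> dplyr::arrange(.data$u, .data$p)
}

# Chains as seen by the regioisomer engine: resolved chains as-is; a sum
# composition collapses to one pseudo-chain carrying the summed double
# bonds, with the longest admissible chain length.
.candidate_chains <- function(ann) {
  if (!ann$sum_composition_only) return(ann$chains)
  n_exp <- if (ann$lipid_class %in% .diacyl_classes) 2L else 1L
  c_tot <- total_carbons(ann)
  list(list(carbons = c_tot - 2L * (n_exp - 1L),
            double_bonds = total_double_bonds(ann),
            n_positions = integer(0)))
}

#' Detect diagnostic-ion events in PRM scans
#'
#' For every legal cleavage coordinate (p, u) of the species, matches
#' all class diagnostic roles in the PRM MS2 scans assigned to the
#' species' target. An event is called detected when at least
#' `min_roles` roles match in the same scan, in at least `min_scans`
#' scans.
#'
#' @param run `ms_run`.
#' @param annotation Species (string or `lipid_annotation`).
#' @param prm_scans Scan subset for this target (tibble with `scan_id`,
#'   `rt`), e.g. from [assign_prm_scans()]; NULL takes every MS2 scan
#'   whose precursor is within `precursor_tol` of the species' target.
#' @param tol_ppm MS2 match tolerance in ppm (default 10).
#' @param min_roles Roles required to co-occur in a scan (default 2).
#' @param min_scans Qualifying scans required (default 3).
#' @param rules Class rule table.
#' @param position_bounds Position legality bounds.
#' @param precursor_tol Precursor tolerance in Th when `prm_scans` is
#'   NULL (default 0.5).
#' @return Tibble of detected events: `p`, `u`, `n_scans`,
#'   `total_intensity`, `roles_matched` (max roles seen in one scan),
#'   `scans` (nested per-scan tibble: `scan_id`, `rt`, `n_roles`,
#'   `intensity`, `qualifies`).
#' @export
detect_events <- function(run, annotation, prm_scans = NULL, tol_ppm = 10,
                          min_roles = 2, min_scans = 3,
                          rules = class_rules(),
                          position_bounds = position_rules(),
                          precursor_tol = 0.5) {
  ann <- .as_lipid(annotation)
  rule <- .class_rule(ann$lipid_class, rules)
  empty <- tibble::tibble(p = integer(), u = integer(),
                          n_scans = integer(), total_intensity = numeric(),
                          roles_matched = integer(), scans = list())
  if (total_double_bonds(ann) == 0) return(empty)
  if (is.null(prm_scans)) {
    target_mz <- oznox_precursor(ann, "+")$mz
    prm_scans <- run$scans[run$scans$ms_level == 2 &
                             abs(run$scans$precursor_mz - target_mz) <=
                             precursor_tol, ]
  }
  if (nrow(prm_scans) == 0) {
    stop("no PRM scans for ", format(ann), call. = FALSE)
  }
  pk <- run$peaks[run$peaks$scan_id %in% prm_scans$scan_id, ]
  grid <- legal_events(ann, position_bounds)
  if (nrow(grid) == 0) return(empty)

  n_roles_class <- length(.class_ms2_roles(rule))
  min_roles_eff <- min(min_roles, n_roles_class)

  events <- purrr::pmap(grid, function(p, u) {
    ions <- .ms2_for_cleavage(ann, p, u, rule)
    hits <- .match_targets(pk, ions$mz, tol_ppm)
    if (nrow(hits) == 0) return(NULL)
    per_scan <- hits |>
      dplyr::group_by(.data$scan_id) |>
      dplyr::summarise(n_roles = dplyr::n_distinct(.data$target_id),
                       intensity = sum(.data$intensity), .groups = "drop") |>
      dplyr::mutate(qualifies = .data$n_roles >= min_roles_eff) |>
      dplyr::left_join(prm_scans[, c("scan_id", "rt")], by = "scan_id") |>
      dplyr::select("scan_id", "rt", "n_roles", "intensity", "qualifies")
    n_q <- sum(per_scan$qualifies)
    if (n_q < min_scans) return(NULL)
    tibble::tibble(
      p = p, u = u, n_scans = n_q,
      total_intensity = sum(per_scan$intensity[per_scan$qualifies]),
      roles_matched = max(per_scan$n_roles),
      scans = list(per_scan)
    )
  })
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$u, .data$p)
}
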