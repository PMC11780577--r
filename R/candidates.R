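# Combinatorial regioisomer candidate enumeration.
#
# A candidate assigns each chain a complete, ordered set of double-bond
# positions drawn from the detected (p, u) events, subject to the
# chaining constraints: the k-th C=C from the methyl end must carry
# u = k - 1 (the count of lower-position C=C lost with the methyl-side
# fragment), positions strictly increase with the minimum spacing, and
# each stays within the chain's legal range.

# All position patterns for one chain drawn from `events` (tibble p, u).
.chain_patterns <- function(carbons, d, events, rules) {
  if (d == 0) return(list(integer(0)))
  recurse <- function(k, last_p) {
    lo <- max(rules$min_n, last_p + rules$min_spacing)
    hi <- carbons - 2L - rules$min_spacing * (d - k)
    opts <- events$p[events$u == k - 1L & events$p >= lo & events$p <= hi]
    if (k == d) return(lapply(opts, function(p) p))
    out <- list()
    for (p in opts) {
      for (tail in recurse(k + 1L, p)) {
        out[[length(out) + 1L]] <- c(p, tail)
      }
    }
    out
  }
  recurse(1L, -Inf)
}

.candidate_label <- function(ann, chains, patterns) {
  if (ann$sum_composition_only) {
    ch <- chains[[1]]
    pos <- patterns[[1]]
    return(paste0(ann$lipid_class, " ", total_carbons(ann), ":",
                  total_double_bonds(ann),
                  if (length(pos)) paste0("(n-", paste(pos, collapse = ","),
                                          ")") else ""))
  }
  ann2 <- ann
  for (i in seq_along(patterns)) {
    ann2$chains[[i]]$n_positions <- as.integer(patterns[[i]])
  }
  format(ann2)
}

#' Enumerate logically valid regioisomer candidates
#'
#' All assignments of detected (p, u) events to the species' chains such
#' that each chain receives exactly its double-bond count of events
#' under the chaining constraints. Candidates whose expected-ion
#' multisets coincide (e.g. two chains swapping equal position sets)
#' are merged into one equivalence class with `ambiguous_chains = TRUE`.
#'
#' @param annotation Species (string or `lipid_annotation`); chain
#'   carbon/double-bond counts are used, any nominal positions are
#'   ignored.
#' @param detected Tibble with columns `p`, `u` (e.g. from
#'   [detect_events()]).
#' @param rules Position legality bounds.
#' @param max_candidates When the merged candidate list exceeds this cap
#'   (default 500) a warning is raised; downstream quantification should
#'   then be skipped in favour of reporting scores only.
#' @return Tibble: `candidate`, `positions` (list of per-chain integer
#'   vectors), `expected` (list tibble `p`, `u`, `degenerate`),
#'   `signature`, `n_events`, `ambiguous_chains`, `over_cap`.
#'   Zero rows when no assignment is consistent.
#' @export
enumerate_candidates <- function(annotation, detected,
                                 rules = position_rules(),
                                 max_candidates = 500) {
  ann <- .as_lipid(annotation)
  chains <- .candidate_chains(ann)
  empty <- tibble::tibble(candidate = character(), positions = list(),
                          expected = list(), signature = character(),
                          n_events = integer(), ambiguous_chains = logical(),
                          over_cap = logical())
  if (nrow(detected) == 0) return(empty)
  per_chain <- lapply(chains, function(ch) {
    .chain_patterns(ch$carbons, ch$double_bonds, detected, rules)
  })
  if (any(lengths(per_chain) == 0)) return(empty)

  idx <- expand.grid(lapply(per_chain, seq_along))
  rows <- purrr::pmap(idx, function(...) {
    picks <- list(...)
    patterns <- purrr::map2(per_chain, picks, ~ .x[[.y]])
    ev <- purrr::map_dfr(patterns, function(pos) {
      if (length(pos) == 0) return(NULL)
      tibble::tibble(p = as.integer(pos), u = seq_along(pos) - 1L)
    })
    ev <- dplyr::arrange(ev, .data$u, .data$p)
    sig <- paste(ev$p, ev$u, sep = "/", collapse = ";")
    exp_ev <- ev |>
      dplyr::group_by(.data$p, .data$u) |>
      dplyr::summarise(degenerate = dplyr::n() > 1, .groups = "drop")
    tibble::tibble(
      candidate = .candidate_label(ann, chains, patterns),
      positions = list(patterns),
      expected = list(exp_ev),
      signature = sig,
      n_events = nrow(exp_ev)
    )
  })
  out <- dplyr::bind_rows(rows)
  merged <- out |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      candidate = dplyr::first(.data$candidate),
      positions = list(dplyr::first(.data$positions)),
      expected = list(dplyr::first(.data$expected)),
      n_events = dplyr::first(.data$n_events),
      ambiguous_chains = dplyr::n() > 1,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$signature) |>
    dplyr::select("candidate", "positions", "expected", "signature",
                  "n_events", "ambiguous_chains")
  merged$over_cap <- nrow(merged) > max_candidates
  if (nrow(merged) > max_candidates) {
    warning("candidate list exceeds cap (", nrow(merged), " > ",
            max_candidates, "); report scores without quantification",
            call. = FALSE)
  }
  merged
}
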