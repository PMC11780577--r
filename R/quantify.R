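# Partitioning lipid signal across regioisomers, isotope correction,
# and single-point internal-standard quantification.

#' Partition lipid signal across regioisomer candidates
#'
#' Under the assumption that diagnostic-ion yield is independent of C=C
#' position: when every candidate owns at least one unique event (an
#' event no other candidate expects), abundance is proportional to the
#' mean summed intensity of its unique events; otherwise a non-negative
#' least-squares system `A x = b` is solved, with `A[event, candidate]`
#' = 1 where expected and `b` the event intensities (undetected expected
#' events enter as zeros). Isomers below the relative-abundance floor
#' (default 1%) are pruned once and the survivors renormalized to 100%.
#'
#' @param candidates Scored candidates ([score_candidates()] output) —
#'   the surviving set.
#' @param detected Detected events ([detect_events()] output).
#' @param prune_pct Relative-abundance floor in percent (default 1).
#' @return Tibble: `candidate`, `signature`, `raw_relative` (percent,
#'   before pruning), `relative_abundance` (percent, after pruning and
#'   renormalization; 0 for pruned rows), `basis` (`unique_ion`,
#'   `least_squares` or `single_candidate`), `pruned`. Non-pruned
#'   abundances sum to 100.
#' @export
partition_abundances <- function(candidates, detected, prune_pct = 1) {
  stopifnot(nrow(candidates) >= 1)
  n <- nrow(candidates)
  ev_key <- paste(detected$p, detected$u, sep = "/")
  ev_int <- stats::setNames(detected$total_intensity, ev_key)

  if (n == 1) {
    w <- 1
    basis <- "single_candidate"
  } else {
    exp_keys <- purrr::map(candidates$expected,
                           ~ paste(.x$p, .x$u, sep = "/"))
    counts <- table(unlist(purrr::map(exp_keys, unique)))
    unique_ev <- names(counts)[counts == 1]
    has_unique <- vapply(exp_keys, function(k) any(k %in% unique_ev),
                         logical(1))
    if (all(has_unique)) {
      basis <- "unique_ion"
      w <- vapply(exp_keys, function(k) {
        mine <- intersect(k, unique_ev)
        mean(ifelse(mine %in% names(ev_int), ev_int[mine], 0))
      }, numeric(1))
    } else {
      basis <- "least_squares"
      all_ev <- sort(unique(unlist(exp_keys)))
      A <- matrix(0, nrow = length(all_ev), ncol = n,
                  dimnames = list(all_ev, NULL))
      for (j in seq_len(n)) A[exp_keys[[j]], j] <- 1
      b <- ifelse(all_ev %in% names(ev_int), ev_int[all_ev], 0)
      w <- pracma::lsqnonneg(A, as.numeric(b))$x
    }
  }
  if (sum(w) == 0) w <- rep(1 / n, n)
  raw <- 100 * w / sum(w)
  pruned <- raw < prune_pct
  if (all(pruned)) pruned <- raw < max(raw)  # keep the best candidate
  rel <- ifelse(pruned, 0, raw)
  rel <- 100 * rel / sum(rel)
  tibble::tibble(
    candidate = candidates$candidate,
    signature = candidates$signature,
    raw_relative = raw,
    relative_abundance = rel,
    basis = basis,
    pruned = pruned
  )
}

#' Type I carbon-13 isotope correction
#'
#' Scales a monoisotopic peak area for the signal fraction lost to
#' natural 13C isotopologues: `auc / (1 - 0.0107)^nC`. Contributions of
#' 2H, 15N and 18O are neglected.
#'
#' @param auc Area under the curve (>= 0).
#' @param formula Elemental composition, formula string, or a bare
#'   carbon count.
#' @param c13_abundance Natural 13C abundance (default 0.0107).
#' @return Corrected AUC.
#' @examples
#' isotope_correct_type1(1000, "C42H82NO8P")
#' @export
isotope_correct_type1 <- function(auc, formula, c13_abundance = 0.0107) {
  stopifnot(all(auc >= 0))
  n_c <- if (is.numeric(formula)) {
    formula
  } else {
    if (is.character(formula)) formula <- parse_formula(formula)
    if ("C" %in% names(formula)) as.numeric(formula[["C"]]) else 0
  }
  auc / (1 - c13_abundance)^n_c
}

#' Single-point internal-standard quantification
#'
#' `concentration = analyte_auc / is_auc * is_concentration`, the
#' single-point response-factor model against a class-matched spiked
#' (typically deuterated) standard. Both AUCs should already be isotope
#' corrected.
#'
#' @param analyte_auc Corrected analyte AUC.
#' @param is_auc Corrected internal-standard AUC (> 0).
#' @param is_concentration Known standard concentration (amount/volume).
#' @return Concentration in the standard's units.
#' @export
absolute_quant <- function(analyte_auc, is_auc, is_concentration) {
  if (any(!is.finite(is_auc)) || any(is_auc <= 0)) {
    stop("internal standard AUC must be positive", call. = FALSE)
  }
  analyte_auc / is_auc * is_concentration
}

#' Spread a lipid concentration across its regioisomers
#'
#' @param abundances Tibble from [partition_abundances()].
#' @param lipid_concentration Total concentration of the lipid feature.
#' @return `abundances` with an added `concentration` column summing to
#'   `lipid_concentration` over non-pruned rows.
#' @export
isomer_concentrations <- function(abundances, lipid_concentration) {
  dplyr::mutate(abundances,
                concentration = lipid_concentration *
                  .data$relative_abundance / 100)
}
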