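# Scan-by-scan probability scoring of regioisomer candidates.
#
# Per scan s: score(R, s) = coverage(R, s) * purity(R, s), where
# coverage is the fraction of R's expected events detected in s and
# purity the fraction of the scan's detected diagnostic intensity that
# R explains. Candidate score is the intensity-weighted mean over scans;
# probabilities normalize scores to sum 1. The construction is
# scale-invariant and reduces to certainty for a candidate that alone
# explains every ion.

#' Score regioisomer candidates scan-by-scan
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param detected Tibble from [detect_events()] (with nested `scans`).
#' @param probability_floor Candidates below this probability are
#'   dropped before quantification (default 0.01); probabilities are
#'   renormalized over the survivors. Set 0 to keep all.
#' @return `candidates` with added `score`, `probability`,
#'   `n_scans_support`, `n_unique_events`, sorted by decreasing
#'   probability.
#' @export
score_candidates <- function(candidates, detected,
                             probability_floor = 0.01) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, score = numeric(0),
                         probability = numeric(0),
                         n_scans_support = integer(0),
                         n_unique_events = integer(0)))
  }
  stopifnot(nrow(detected) > 0)
  ev_key <- paste(detected$p, detected$u, sep = "/")

  # per-scan presence/intensity matrix of detected events
  per_scan <- purrr::map2_dfr(detected$scans, ev_key, function(sc, key) {
    sc <- sc[sc$qualifies, ]
    if (nrow(sc) == 0) return(NULL)
    tibble::tibble(event = key, scan_id = sc$scan_id,
                   intensity = sc$intensity)
  })
  scan_tot <- per_scan |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")

  scored <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    exp_ev <- candidates$expected[[i]]
    keys <- paste(exp_ev$p, exp_ev$u, sep = "/")
    mine <- per_scan[per_scan$event %in% keys, ] |>
      dplyr::group_by(.data$scan_id) |>
      dplyr::summarise(n_present = dplyr::n_distinct(.data$event),
                       explained = sum(.data$intensity), .groups = "drop")
    df <- dplyr::left_join(scan_tot, mine, by = "scan_id") |>
      tidyr::replace_na(list(n_present = 0L, explained = 0))
    cov <- df$n_present / length(keys)
    pur <- ifelse(df$total > 0, df$explained / df$total, 0)
    w <- df$total
    score <- if (sum(w) > 0) sum(w * cov * pur) / sum(w) else 0
    tibble::tibble(score = score, n_scans_support = sum(df$n_present > 0))
  })
  out <- dplyr::bind_cols(candidates, scored)
  tot <- sum(out$score)
  out$probability <- if (tot > 0) out$score / tot else
    rep(1 / nrow(out), nrow(out))
  if (probability_floor > 0) {
    keep <- out$probability >= probability_floor
    if (!any(keep)) keep <- out$probability == max(out$probability)
    out <- out[keep, ]
    out$probability <- out$probability / sum(out$probability)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$probability),
                        .data$signature)
  out$n_unique_events <- .count_unique_events(out)
  out
}

# events expected by exactly one surviving candidate
.count_unique_events <- function(candidates) {
  all_ev <- purrr::imap_dfr(candidates$expected, function(ev, i) {
    tibble::tibble(event = paste(ev$p, ev$u, sep = "/"), cand = i)
  })
  uniq <- all_ev |>
    dplyr::group_by(.data$event) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  vapply(seq_len(nrow(candidates)), function(i) {
    sum(uniq$cand == i)
  }, integer(1))
}

#' Merge candidate scores across replicate runs
#'
#' Weighted mean of per-run candidate scores, weights proportional to
#' each run's total detected diagnostic intensity (equal weights if all
#' intensities are zero). A candidate absent from a run contributes 0
#' for that run. Probabilities are re-normalized after merging.
#'
#' @param scored_runs List of scored candidate tibbles (from
#'   [score_candidates()], one per run).
#' @param weights Optional numeric per-run weights; default each run's
#'   summed `total_intensity`-weighted support, i.e. the sum of
#'   `score * 0 +` run diagnostic intensity. Supply explicitly when the
#'   detected-event tables are not at hand.
#' @param run_intensity Numeric vector of per-run total diagnostic
#'   intensities (preferred way to set weights).
#' @return Merged tibble: `candidate`, `signature`, `score`,
#'   `probability`, `n_runs`.
#' @export
align_replicates <- function(scored_runs, weights = NULL,
                             run_intensity = NULL) {
  stopifnot(length(scored_runs) >= 1)
  if (is.null(weights)) {
    weights <- if (!is.null(run_intensity)) run_intensity
    else rep(1, length(scored_runs))
  }
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  weights <- weights / sum(weights)
  long <- purrr::imap_dfr(scored_runs, function(df, i) {
    if (nrow(df) == 0) return(NULL)
    tibble::tibble(candidate = df$candidate, signature = df$signature,
                   score = df$score, run = i)
  })
  if (nrow(long) == 0) {
    return(tibble::tibble(candidate = character(), signature = character(),
                          score = numeric(), probability = numeric(),
                          n_runs = integer()))
  }
  merged <- long |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      candidate = dplyr::first(.data$candidate),
      score = sum(.data$score * weights[.data$run]),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
  tot <- sum(merged$score)
  merged$probability <- if (tot > 0) merged$score / tot else
    rep(1 / nrow(merged), nrow(merged))
  dplyr::arrange(merged, dplyr::desc(.data$probability)) |>
    dplyr::select("candidate", "signature", "score", "probability",
                  "n_runs")
}
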