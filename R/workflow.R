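# End-to-end annotation workflow: detect diagnostic ions, enumerate and
# score regioisomer candidates, partition lipid signal.

#' Annotate lipid C=C regioisomers in an LC-MS run
#'
#' Runs the full pipeline for every annotation: PRM scan assignment,
#' diagnostic-ion detection, combinatorial candidate enumeration,
#' scan-by-scan scoring, and abundance partitioning. Species whose
#' candidate list exceeds the configured cap are reported with scores
#' but no abundances; species without detections are flagged.
#'
#' @param run `ms_run` (or a file path readable by [read_run()]).
#' @param annotations Annotation tibble from [parse_annotations()] /
#'   [read_annotations()] (or input they accept); retention times
#'   required.
#' @param config `oznox_config`.
#' @return Object of class `oznox_result`: list with `annotations`,
#'   `targets`, `ms1_products` (MS1 ozonolysis-feature survey),
#'   `events` (detected MS2 events per annotation), `candidates`
#'   (scored), `abundances`, `outcomes` (per-annotation status), and
#'   `config`.
#' @export
annotate_run <- function(run, annotations, config = oznox_config()) {
  if (is.character(run)) run <- read_run(run)
  stopifnot(inherits(run, "ms_run"))
  if (!is.data.frame(annotations)) {
    annotations <- parse_annotations(annotations)
  }
  pos_rules <- .position_rules_from(config)
  targets <- build_prm_targets(annotations,
                               rt_window_min = config$rt_window_min,
                               ammoniate = config$ammoniate)
  assigned <- assign_prm_scans(run, targets)

  n_ann <- nrow(annotations)
  events_l <- vector("list", n_ann); cands_l <- vector("list", n_ann)
  abund_l <- vector("list", n_ann); ms1_l <- vector("list", n_ann)
  outcome_l <- vector("list", n_ann)
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations$lipid[[i]]
    lab <- annotations$annotation[i]
    status <- "not_detected"
    if (total_double_bonds(ann) == 0) {
      outcome_l[[i]] <- tibble::tibble(annotation = lab,
                                       outcome = "saturated",
                                       n_events = 0L, n_candidates = 0L)
      next
    }
    # MS1 ozonolysis-product survey (when positions are stated)
    if (positions_complete(ann)) {
      rt_win <- c(ann$retention_time - config$rt_window_min,
                  ann$retention_time + config$rt_window_min)
      ms1_l[[i]] <- ozesi_products(ann, "+") |>
        dplyr::rowwise() |>
        dplyr::mutate(.eic = list(extract_eic(run, .data$mz,
                                              tol_ppm = config$ms1_tol_ppm,
                                              rt_range = rt_win))) |>
        dplyr::ungroup() |>
        dplyr::mutate(annotation = lab,
                      apex_rt = vapply(.data$.eic, attr, numeric(1),
                                       "apex_rt"),
                      area = vapply(.data$.eic, attr, numeric(1), "area"),
                      detected = .data$area > 0) |>
        dplyr::select("annotation", "role", "p", "u", "mz", "apex_rt",
                      "area", "detected")
    }
    sc <- assigned[assigned$annotation == lab, ]
    if (nrow(sc) > 0) {
      det <- detect_events(run, ann, prm_scans = sc,
                           tol_ppm = config$ms2_tol_ppm,
                           min_roles = config$min_roles,
                           min_scans = config$min_scans,
                           position_bounds = pos_rules)
      if (nrow(det) > 0) {
        events_l[[i]] <- dplyr::mutate(det, annotation = lab, .before = 1)
        cand <- enumerate_candidates(ann, det, rules = pos_rules,
                                     max_candidates = config$max_candidates)
        if (nrow(cand) > 0) {
          scored <- score_candidates(cand, det,
                                     probability_floor =
                                       config$probability_floor)
          cands_l[[i]] <- dplyr::mutate(scored, annotation = lab,
                                        .before = 1)
          if (!any(scored$over_cap)) {
            ab <- partition_abundances(scored, det,
                                       prune_pct = config$prune_pct)
            abund_l[[i]] <- dplyr::mutate(ab, annotation = lab,
                                          .before = 1)
            status <- "confirmed"
          } else {
            status <- "candidates_only"
          }
        } else {
          status <- "no_valid_candidate"
        }
      }
    }
    outcome_l[[i]] <- tibble::tibble(
      annotation = lab, outcome = status,
      n_events = if (is.null(events_l[[i]])) 0L else nrow(events_l[[i]]),
      n_candidates = if (is.null(cands_l[[i]])) 0L else
        nrow(cands_l[[i]])
    )
  }

  structure(list(
    annotations = annotations,
    targets = targets,
    ms1_products = dplyr::bind_rows(ms1_l),
    events = dplyr::bind_rows(events_l),
    candidates = dplyr::bind_rows(cands_l),
    abundances = dplyr::bind_rows(abund_l),
    outcomes = dplyr::bind_rows(outcome_l),
    config = config
  ), class = "oznox_result")
}

#' @export
print.oznox_result <- function(x, ...) {
  cat("<oznox_result> ", nrow(x$annotations), " annotation(s): ",
      sum(x$outcomes$outcome == "confirmed"), " confirmed, ",
      sum(x$outcomes$outcome == "candidates_only"), " candidates-only, ",
      sum(!x$outcomes$outcome %in% c("confirmed", "candidates_only")),
      " other\n", sep = "")
  if (nrow(x$abundances) > 0) {
    print(tidy(x), n = 20)
  }
  invisible(x)
}

#' Tidy the per-isomer quantification of a result
#'
#' @param x `oznox_result`.
#' @param ... Unused.
#' @return Tibble: one row per (annotation, candidate isomer) with
#'   relative abundances, probability and support.
#' @method tidy oznox_result
#' @export
tidy.oznox_result <- function(x, ...) {
  if (nrow(x$abundances) == 0) {
    return(tibble::tibble(annotation = character(), candidate = character(),
                          probability = numeric(), raw_relative = numeric(),
                          relative_abundance = numeric(), basis = character(),
                          pruned = logical()))
  }
  dplyr::left_join(
    x$abundances,
    dplyr::select(x$candidates, "annotation", "signature", "probability",
                  "n_scans_support"),
    by = c("annotation", "signature")
  ) |>
    dplyr::select("annotation", "candidate", "probability",
                  "raw_relative", "relative_abundance", "basis", "pruned",
                  "n_scans_support")
}

#' One-row summary of a result
#' @inheritParams tidy.oznox_result
#' @return One-row tibble with annotation/outcome counts.
#' @method glance oznox_result
#' @export
glance.oznox_result <- function(x, ...) {
  outcome <- if ("outcome" %in% names(x$outcomes)) x$outcomes$outcome
  else character(0)
  tibble::tibble(
    n_annotations = nrow(x$annotations),
    n_confirmed = sum(outcome == "confirmed"),
    n_candidates_only = sum(outcome == "candidates_only"),
    n_not_detected = sum(outcome == "not_detected"),
    n_events = nrow(x$events),
    n_isomers_reported = if ("pruned" %in% names(x$abundances)) {
      sum(!x$abundances$pruned)
    } else 0L
  )
}

#' Write the report tables of a result
#'
#' Four TSV tables — MS1 ozonolysis products, detected MS2 events,
#' scored regioisomer candidates, quantified isomers — plus a JSON run
#' summary, in deterministic order (annotation, then candidate
#' positions).
#'
#' @param result `oznox_result`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "oznox_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ms1_products = file.path(dir, "ms1_products.tsv"),
    ms2_products = file.path(dir, "ms2_products.tsv"),
    candidates = file.path(dir, "regioisomer_candidates.tsv"),
    quantities = file.path(dir, "isomer_quantities.tsv"),
    summary = file.path(dir, "summary.json")
  )
  ms1 <- result$ms1_products
  if (nrow(ms1) == 0) {
    ms1 <- tibble::tibble(annotation = character(), role = character(),
                          p = integer(), u = integer(), mz = numeric(),
                          apex_rt = numeric(), area = numeric(),
                          detected = logical())
  }
  readr::write_tsv(dplyr::arrange(ms1, .data$annotation, .data$p,
                                  .data$role),
                   paths[["ms1_products"]], progress = FALSE)

  ev <- result$events
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(annotation = character(), p = integer(),
                         u = integer(), n_scans = integer(),
                         total_intensity = numeric(),
                         roles_matched = integer())
  } else {
    ev <- dplyr::select(ev, -"scans")
  }
  readr::write_tsv(dplyr::arrange(ev, .data$annotation, .data$u, .data$p),
                   paths[["ms2_products"]], progress = FALSE)

  cand <- result$candidates
  if (nrow(cand) == 0) {
    cand <- tibble::tibble(annotation = character(), candidate = character(),
                           score = numeric(), probability = numeric(),
                           n_unique_events = integer(),
                           n_scans_support = integer())
  } else {
    cand <- dplyr::select(cand, "annotation", "candidate", "score",
                          "probability", "n_unique_events",
                          "n_scans_support")
  }
  readr::write_tsv(dplyr::arrange(cand, .data$annotation, .data$candidate),
                   paths[["candidates"]], progress = FALSE)

  ab <- result$abundances
  if (nrow(ab) == 0) {
    ab <- tibble::tibble(annotation = character(), candidate = character(),
                         raw_relative = numeric(),
                         relative_abundance = numeric(),
                         basis = character(), pruned = logical())
  } else {
    ab <- dplyr::select(ab, "annotation", "candidate", "raw_relative",
                        "relative_abundance", "basis", "pruned")
  }
  readr::write_tsv(dplyr::arrange(ab, .data$annotation, .data$candidate),
                   paths[["quantities"]], progress = FALSE)

  jsonlite::write_json(
    c(as.list(glance(result)),
      list(outcomes = result$outcomes, config = unclass(result$config))),
    paths[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
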