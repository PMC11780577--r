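# Run configuration: tolerances and thresholds shared by the workflow
# and the command-line interface.

#' Default workflow configuration
#'
#' @param ms1_tol_ppm MS1 match tolerance in ppm (default 5, suited to
#'   30k-resolution data).
#' @param ms2_tol_ppm MS2 match tolerance in ppm (default 10).
#' @param min_roles Diagnostic roles required to co-occur in one scan
#'   (default 2).
#' @param min_scans Qualifying scans required per event (default 3).
#' @param probability_floor Candidate probability floor (default 0.01).
#' @param prune_pct Relative-abundance pruning floor in percent
#'   (default 1).
#' @param rt_window_min PRM RT half-window in minutes (default 0.5).
#' @param max_candidates Candidate cap above which quantification is
#'   skipped (default 500).
#' @param ammoniate Ammoniate the derivatized precursor for
#'   ammonium-adduct classes (default TRUE).
#' @param min_n,min_spacing Double-bond position legality bounds.
#' @return Named list of class `oznox_config`.
#' @export
oznox_config <- function(ms1_tol_ppm = 5, ms2_tol_ppm = 10, min_roles = 2,
                         min_scans = 3, probability_floor = 0.01,
                         prune_pct = 1, rt_window_min = 0.5,
                         max_candidates = 500, ammoniate = TRUE,
                         min_n = 2, min_spacing = 2) {
  stopifnot(ms1_tol_ppm > 0, ms2_tol_ppm > 0, min_roles >= 1,
            min_scans >= 1, probability_floor >= 0,
            probability_floor < 1, prune_pct >= 0, prune_pct < 100,
            rt_window_min > 0, max_candidates >= 1)
  structure(list(ms1_tol_ppm = ms1_tol_ppm, ms2_tol_ppm = ms2_tol_ppm,
                 min_roles = as.integer(min_roles),
                 min_scans = as.integer(min_scans),
                 probability_floor = probability_floor,
                 prune_pct = prune_pct, rt_window_min = rt_window_min,
                 max_candidates = as.integer(max_candidates),
                 ammoniate = isTRUE(ammoniate),
                 min_n = as.integer(min_n),
                 min_spacing = as.integer(min_spacing)),
            class = "oznox_config")
}

#' Read / write a configuration as JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults, so a
#' config file round-trips through [write_config()] and
#' [read_config()].
#'
#' @param path JSON file path.
#' @return `oznox_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(oznox_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(oznox_config, vals)
}

#' @rdname read_config
#' @param config `oznox_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

.position_rules_from <- function(config) {
  list(min_n = config$min_n, min_spacing = config$min_spacing)
}
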