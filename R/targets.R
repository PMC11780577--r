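# PRM target list generation.

#' Default normalized collision energies per lipid class
#'
#' Class optima for fragmenting the nitrogen-oxide precursor adduct:
#' FA 10, PC 15, PE 25, LPE 15, PG 25, PI 23, PS 23, LPG 23, PA 29.
#' LPC is not separately stated and inherits the PC value.
#'
#' @return Named numeric vector, class -> NCE.
#' @export
nce_table <- function() {
  r <- class_rules()
  stats::setNames(r$nce, r$lipid_class)
}

#' Build a PRM target list
#'
#' One scheduled MS2 target per unsaturated annotation: the positive-mode
#' derivatized precursor m/z, a retention-time window around the stated
#' RT, and the class collision energy. Overlapping windows are allowed.
#'
#' @param annotations Tibble from [parse_annotations()] (or input it
#'   accepts); every row must have a retention time.
#' @param rt_window_min Half-width of the RT window in minutes
#'   (default 0.5).
#' @param nce Named class -> NCE vector, defaults to [nce_table()].
#' @param ammoniate Passed to [oznox_precursor()].
#' @return Tibble sorted by RT: `mz`, `polarity`, `rt_start_min`,
#'   `rt_end_min`, `nce`, `annotation`.
#' @export
build_prm_targets <- function(annotations, rt_window_min = 0.5,
                              nce = nce_table(), ammoniate = TRUE) {
  if (!is.data.frame(annotations)) {
    annotations <- parse_annotations(annotations)
  }
  unsat <- annotations[annotations$total_double_bonds > 0, ]
  if (nrow(unsat) == 0) {
    return(tibble::tibble(mz = numeric(), polarity = character(),
                          rt_start_min = numeric(), rt_end_min = numeric(),
                          nce = numeric(), annotation = character()))
  }
  if (any(!is.finite(unsat$retention_time))) {
    stop("annotation(s) without retention time: ",
         paste(unsat$annotation[!is.finite(unsat$retention_time)],
               collapse = "; "), call. = FALSE)
  }
  purrr::map2_dfr(unsat$lipid, unsat$annotation, function(ann, lab) {
    tibble::tibble(
      mz = oznox_precursor(ann, "+", ammoniate = ammoniate)$mz,
      polarity = "+",
      rt_start_min = ann$retention_time - rt_window_min,
      rt_end_min = ann$retention_time + rt_window_min,
      nce = unname(nce[[ann$lipid_class]]),
      annotation = lab
    )
  }) |>
    dplyr::arrange(.data$rt_start_min, .data$mz)
}

#' Write a PRM target list as TSV
#' @param targets Tibble from [build_prm_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prm_targets <- function(targets, path) {
  readr::write_tsv(targets, path, progress = FALSE)
  invisible(path)
}
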