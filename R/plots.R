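# ggplot2 displays for chromatograms and isomer abundances.

#' Plot an extracted ion chromatogram
#'
#' @param object `oznox_eic` from [extract_eic()].
#' @param ... Unused.
#' @return ggplot.
#' @method autoplot oznox_eic
#' @export
autoplot.oznox_eic <- function(object, ...) {
  apex <- attr(object, "apex_rt")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rt,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity",
      title = sprintf("EIC m/z %.4f (± %g ppm)",
                      attr(object, "target_mz"), attr(object, "tol_ppm"))
    )
  if (is.finite(apex)) {
    p <- p + ggplot2::geom_vline(xintercept = apex, linetype = "dotted")
  }
  p
}

#' Plot per-isomer relative abundances of a result
#'
#' One bar per surviving regioisomer, faceted by annotation; pruned
#' candidates are dropped.
#'
#' @param result `oznox_result` (or a [partition_abundances()] tibble
#'   with an `annotation` column).
#' @return ggplot.
#' @export
plot_isomer_abundances <- function(result) {
  ab <- if (inherits(result, "oznox_result")) result$abundances else result
  ab <- ab[!ab$pruned, ]
  ggplot2::ggplot(ab, ggplot2::aes(x = .data$candidate,
                                   y = .data$relative_abundance)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$annotation), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_isomer_abundances
#' @param object `oznox_result`.
#' @param ... Unused.
#' @method autoplot oznox_result
#' @export
autoplot.oznox_result <- function(object, ...) {
  plot_isomer_abundances(object)
}

#' Plot detected MS2 diagnostic events
#'
#' Stem plot of summed event intensity by cleavage position, per
#' annotation.
#'
#' @param result `oznox_result` or a [detect_events()] tibble.
#' @return ggplot.
#' @export
plot_detected_events <- function(result) {
  ev <- if (inherits(result, "oznox_result")) result$events else result
  if (!"annotation" %in% names(ev)) ev$annotation <- "events"
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$p,
                                   y = .data$total_intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$p, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$annotation), scales = "free") +
    ggplot2::labs(x = "n-position of cleaved C=C",
                  y = "summed diagnostic intensity")
}
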