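# Adduct registry and m/z arithmetic.
#
# m/z = (neutral mass + delta mass - charge * electron mass) / |charge|
# i.e. a +1 adduct is lighter than the neutral-plus-delta by one electron,
# a -1 adduct heavier by one.

.adduct_registry <- local({
  reg <- list(
    "[M+H]+"         = list(delta = c(H = 1L), charge = +1L),
    "[M+NH4]+"       = list(delta = c(N = 1L, H = 4L), charge = +1L),
    "[M-H]-"         = list(delta = c(H = -1L), charge = -1L),
    # nitrogen-oxide derivatization adducts of the lipid ozonide
    "[M+NO4-H]+"     = list(delta = c(N = 1L, O = 4L, H = -1L), charge = +1L),
    "[M+NO4-H+NH3]+" = list(delta = c(N = 2L, O = 4L, H = 2L), charge = +1L),
    "[M+N2O7]-"      = list(delta = c(N = 2L, O = 7L), charge = -1L),
    "[M+N2O7-H]-"    = list(delta = c(N = 2L, O = 7L, H = -1L), charge = -1L),
    # bare ions (delta empty): m/z of a composition that is already charged
    "[M]+"           = list(delta = c(), charge = +1L),
    "[M]-"           = list(delta = c(), charge = -1L)
  )
  reg
})

#' List the registered ionization adducts
#'
#' Includes the conventional ESI adducts and the nitrogen-oxide (OzNOx)
#' adducts of lipid ozonides: `[M+NO4-H]+` (positive mode; `+NH3` variant
#' for ammonium-adduct classes) and `[M+N2O7]-` (negative mode, with the
#' deprotonated `[M+N2O7-H]-` variant also registered).
#'
#' @return Tibble with columns `name`, `delta` (formula string), `charge`.
#' @export
adducts <- function() {
  tibble::tibble(
    name = names(.adduct_registry),
    delta = purrr::map_chr(.adduct_registry, function(a) {
      d <- a$delta
      if (length(d) == 0) return("")
      paste0(ifelse(d > 0, "+", "-"), names(d), abs(d), collapse = "")
    }),
    charge = purrr::map_int(.adduct_registry, "charge")
  )
}

.adduct_spec <- function(adduct) {
  if (is.list(adduct) && all(c("delta", "charge") %in% names(adduct))) {
    return(adduct)
  }
  spec <- .adduct_registry[[adduct]]
  if (is.null(spec)) {
    stop("unknown adduct: ", adduct, call. = FALSE)
  }
  spec
}

#' m/z of an ionized species
#'
#' Applies an adduct's composition delta to a neutral formula, divides by
#' the absolute charge, and corrects for electron mass with the proper
#' sign (a protonated ion is one electron lighter than neutral + H).
#'
#' @param neutral Neutral elemental composition ([el()]) or a formula
#'   string.
#' @param adduct Adduct name (see [adducts()]) or a
#'   `list(delta =, charge =)` spec.
#' @return m/z in Th (Da/charge).
#' @examples
#' adduct_mz(el(N = 1, O = 3), "[M]-") # nitrate anion, 61.9884
#' adduct_mz(parse_formula("C18H34O2"), "[M+NO4-H]+") # 359.2302
#' @export
adduct_mz <- function(neutral, adduct) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  spec <- .adduct_spec(adduct)
  if (abs(spec$charge) < 1) stop("charge must be non-zero", call. = FALSE)
  d <- spec$delta
  ion <- neutral
  if (length(d) > 0) {
    gain <- d[d > 0]
    loss <- -d[d < 0]
    if (length(gain)) ion <- el_add(ion, do.call(el, as.list(gain)))
    if (length(loss)) ion <- el_sub(ion, do.call(el, as.list(loss)))
  }
  (monoisotopic_mass(ion) - spec$charge * ELECTRON_MASS) / abs(spec$charge)
}

#' m/z of the nitrate anion NO3-
#'
#' The base peak of negative-mode MS2 spectra of the `[M+N2O7]-`
#' derivatization adduct; prints as 61.99 at two decimals.
#'
#' @return m/z (numeric scalar).
#' @export
nitrate_mz <- function() {
  adduct_mz(el(N = 1, O = 3), "[M]-")
}
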