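#' Monoisotopic element masses
#'
#' Masses (Da) of the isotopes relevant to glycerophospholipid and fatty
#' acid chemistry: 12C, 1H, 2H (deuterium, symbol "D"), 14N, 16O, 31P.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @export
element_masses <- c(
  C = 12,
  H = 1.0078250319,
  D = 2.0141017780,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

#' Physical constants used in m/z arithmetic
#' @name ion-constants
#' @keywords internal
ELECTRON_MASS <- 0.00054857990946
PROTON_MASS <- element_masses[["H"]] - ELECTRON_MASS

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector of non-negative
#' counts per element symbol (C, H, D, N, O, P). Zero-count elements are
#' dropped so that equal formulas compare equal.
#'
#' @param ... Named integer counts, e.g. `el(C = 18, H = 34, O = 2)`.
#' @return Named integer vector of class `element_counts`.
#' @examples
#' el(C = 9, H = 16, O = 3) # 9-oxononanoic acid
#' @export
el <- function(...) {
  x <- c(...)
  if (length(x) == 0) {
    return(structure(integer(0), class = "element_counts"))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all element counts must be named", call. = FALSE)
  }
  unknown <- setdiff(names(x), names(element_masses))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  x <- x[x != 0]
  storage.mode(x) <- "integer"
  # canonical Hill-ish order keeps formulas comparable with identical()
  ord <- c("C", "H", "D", "N", "O", "P")
  x <- x[order(match(names(x), ord))]
  structure(x, class = "element_counts")
}

#' Add two elemental compositions element-wise
#' @param a,b `element_counts` vectors (or anything `el()` accepts).
#' @return `element_counts`.
#' @export
el_add <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  do.call(el, as.list(out))
}

#' Subtract an elemental composition element-wise
#'
#' Errors if any element count would go negative: a fragment cannot lose
#' atoms its precursor does not have.
#'
#' @inheritParams el_add
#' @return `element_counts`.
#' @export
el_sub <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    stop("subtraction drives element(s) negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(el, as.list(out))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param formula `element_counts` (an empty composition has mass 0).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(el(H = 2, O = 1)) # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (length(formula) == 0) return(0)
  unknown <- setdiff(names(formula), names(element_masses))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(element_masses[names(formula)] * as.numeric(formula))
}

#' Format an elemental composition as a molecular formula string
#' @param x `element_counts`.
#' @param ... Unused.
#' @export
format.element_counts <- function(x, ...) {
  if (length(x) == 0) return("")
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Parse a molecular formula string
#'
#' Accepts formulas like `"C18H34O2"` or `"H2O"`; element symbols are the
#' ones in [element_masses] (single letters plus `D` for deuterium).
#'
#' @param text Formula string.
#' @return `element_counts`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) return(el())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, syms, sum)
  do.call(el, as.list(counts))
}
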