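# Elemental composition of lipid species.
#
# Neutral formula = class core (zero-acyl backbone + headgroup) plus one
# acyl contribution C_c H_(2c-2-2d) O per chain; esterification water loss
# is folded into the core formulas. Deuterium labels substitute D for H
# and are assumed to sit on the backbone/headgroup, so they are retained
# in every carboxyl-side product ion.

.class_cores <- list(
  PC  = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  LPC = c(C = 8, H = 20, N = 1, O = 6, P = 1),
  PE  = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  LPE = c(C = 5, H = 14, N = 1, O = 6, P = 1),
  PG  = c(C = 6, H = 15, O = 8, P = 1),
  LPG = c(C = 6, H = 15, O = 8, P = 1),
  PS  = c(C = 6, H = 14, N = 1, O = 8, P = 1),
  PI  = c(C = 9, H = 19, O = 11, P = 1),
  PA  = c(C = 3, H = 9, O = 6, P = 1),
  FA  = c(H = 2, O = 1)   # free acid: chain contribution + H2O
)

.acyl_contribution <- function(carbons, double_bonds) {
  el(C = carbons, H = 2 * carbons - 2 - 2 * double_bonds, O = 1)
}

#' Neutral elemental composition of a lipid annotation
#'
#' Works for fully resolved species and for sum compositions (the split
#' of carbons across chains does not change the total formula; a diacyl
#' sum composition contributes two ester oxygens).
#'
#' @param annotation `lipid_annotation` or shorthand string.
#' @return `element_counts`.
#' @examples
#' format(composition("FA 18:1(n-9)"))   # "C18H34O2"
#' format(composition("PC 16:0/18:1"))   # "C42H82NO8P"
#' @export
composition <- function(annotation) {
  ann <- .as_lipid(annotation)
  core <- do.call(el, as.list(.class_cores[[ann$lipid_class]]))
  if (is.null(core)) {
    stop("no core formula registered for class ", ann$lipid_class,
         call. = FALSE)
  }
  n_chains_expected <- if (ann$lipid_class %in% .diacyl_classes) 2L else 1L
  out <- core
  if (ann$sum_composition_only) {
    # n_chains_expected acyl groups with the summed carbon/db counts
    c_tot <- total_carbons(ann)
    d_tot <- total_double_bonds(ann)
    out <- el_add(out, el(C = c_tot,
                          H = 2 * c_tot - 2 * d_tot - 2 * n_chains_expected,
                          O = n_chains_expected))
  } else {
    for (ch in ann$chains) {
      out <- el_add(out, .acyl_contribution(ch$carbons, ch$double_bonds))
    }
  }
  if (ann$deuterium_count > 0) {
    out <- el_add(el_sub(out, el(H = ann$deuterium_count)),
                  el(D = ann$deuterium_count))
  }
  out
}

#' Neutral monoisotopic mass of a lipid annotation
#' @inheritParams composition
#' @return Mass in Da.
#' @export
lipid_mass <- function(annotation) {
  monoisotopic_mass(composition(annotation))
}
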