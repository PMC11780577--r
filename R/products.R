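# Theoretical ozonolysis and nitrogen-oxide adduct products.
#
# One cleavage event is a pair (p, u): p the methyl-terminal position of
# the cleaved C=C, u the number of C=C at strictly lower n-# on the same
# chain (lost with the methyl-side fragment). The carboxyl-side product
# keeps the rest of the molecule intact, so its mass change relative to
# the intact species, -C_p H_(2p-2u) + O, does not depend on which chain
# carried the cleaved bond.

#' Class fragmentation rules for derivatized-precursor MS2
#'
#' Per lipid class: the base ionization adduct, the optimum normalized
#' collision energy (NCE), the headgroup neutral loss (positive mode,
#' from the protonated species; ammonium-adduct classes additionally
#' shed NH3, which cancels so the surviving fragment is the same), the
#' diagnostic ion roles emitted per cleavage, and whether the
#' pair retaining the headgroup is emitted alongside (PE).
#'
#' Diagnostic roles per C=C: PC/LPC a pair (aldehyde + loss of CHO);
#' PE the same pair with and without headgroup loss (4 ions); PG, PI,
#' PS, PA, LPG the headgroup-lost pair; LPE a triplet (aldehyde, -H2O,
#' -CHO); FA a trio (ammoniated aldehyde, protonated, -H2O).
#'
#' @return Tibble with one row per class: `lipid_class`, `base_adduct`,
#'   `nce`, `headgroup_loss` (formula string or NA), `roles` (list of
#'   role names), `emit_headgroup_retained_pairs`.
#' @export
class_rules <- function() {
  tibble::tribble(
    ~lipid_class, ~base_adduct, ~nce, ~headgroup_loss, ~roles, ~emit_headgroup_retained_pairs,
    "PC",  "[M+H]+",   15, NA_character_, list(c("ms2_aldehyde", "ms2_aldehyde_minus_CHO")), FALSE,
    "LPC", "[M+H]+",   15, NA_character_, list(c("ms2_aldehyde", "ms2_aldehyde_minus_CHO")), FALSE,
    "PE",  "[M+H]+",   25, "C2H8NO4P",    list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), TRUE,
    "LPE", "[M+H]+",   15, NA_character_, list(c("ms2_aldehyde", "ms2_aldehyde_minus_H2O", "ms2_aldehyde_minus_CHO")), FALSE,
    "PG",  "[M+NH4]+", 25, "C3H9O6P",     list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), FALSE,
    "LPG", "[M+NH4]+", 23, "C3H9O6P",     list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), FALSE,
    "PI",  "[M+NH4]+", 23, "C6H13O9P",    list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), FALSE,
    "PS",  "[M+H]+",   23, "C3H8NO6P",    list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), FALSE,
    "PA",  "[M+H]+",   29, "H3PO4",       list(c("ms2_headgroup_lost", "ms2_headgroup_lost_minus_CHO")), FALSE,
    "FA",  "[M+NH4]+", 10, NA_character_, list(c("ms2_aldehyde_NH4", "ms2_aldehyde", "ms2_aldehyde_minus_H2O")), FALSE
  ) |>
    dplyr::mutate(roles = purrr::map(roles, unlist))
}

.class_rule <- function(lipid_class, rules = class_rules()) {
  row <- rules[rules$lipid_class == lipid_class, ]
  if (nrow(row) != 1) {
    stop("no fragmentation rule registered for class ", lipid_class,
         call. = FALSE)
  }
  row
}

#' Enumerate ozonolysis cleavage events of a position-resolved species
#'
#' One event per C=C per chain; `u` counts the double bonds at lower n-#
#' on the same chain (they leave with the methyl-side fragment). Events
#' sharing (p, u) across chains give products of identical m/z and are
#' flagged `mass_degenerate`.
#'
#' @param annotation `lipid_annotation` (all positions specified) or a
#'   shorthand string.
#' @return Tibble with columns `chain_index`, `p`, `u`,
#'   `mass_degenerate`.
#' @examples
#' enumerate_cleavages("FA 22:4(n-6,9,12,15)")
#' @export
enumerate_cleavages <- function(annotation) {
  ann <- .as_lipid(annotation)
  if (!positions_complete(ann)) {
    stop("annotation has unresolved double-bond positions: ",
         format(ann), call. = FALSE)
  }
  rows <- purrr::imap(ann$chains, function(ch, i) {
    if (ch$double_bonds == 0) return(NULL)
    tibble::tibble(chain_index = i,
                   p = ch$n_positions,
                   u = seq_along(ch$n_positions) - 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(chain_index = integer(), p = integer(),
                          u = integer(), mass_degenerate = logical()))
  }
  out |>
    dplyr::group_by(.data$p, .data$u) |>
    dplyr::mutate(mass_degenerate = dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain_index, .data$p)
}

#' Neutral formula of the carboxyl-side ozonolysis aldehyde
#'
#' @param annotation Resolved or sum-composition species.
#' @param p,u Cleavage coordinates.
#' @return `element_counts` of the neutral aldehyde.
#' @export
aldehyde_formula <- function(annotation, p, u) {
  ann <- .as_lipid(annotation)
  base <- composition(ann)
  el_add(el_sub(base, el(C = p, H = 2 * p - 2 * u)), el(O = 1))
}

#' Theoretical in-source ozonolysis (MS1) products
#'
#' Per cleavage: the ozonolysis aldehyde, ionized with the class base
#' adduct (positive mode) or `[M-H]-` (negative mode), and the Criegee
#' ion one oxygen heavier. Products are de-duplicated by m/z within
#' 1e-6 Da (exact-formula collisions between chains).
#'
#' @param annotation Position-resolved species.
#' @param polarity `"+"` or `"-"`.
#' @param include_criegee Emit the Criegee partner ion (default TRUE).
#' @return Tibble: `role`, `p`, `u`, `formula`, `mz`, `polarity`,
#'   `ms_level` (= 1), `adduct`.
#' @export
ozesi_products <- function(annotation, polarity = c("+", "-"),
                           include_criegee = TRUE) {
  ann <- .as_lipid(annotation)
  polarity <- match.arg(polarity)
  cl <- enumerate_cleavages(ann)
  if (nrow(cl) == 0) {
    return(tibble::tibble(role = character(), p = integer(), u = integer(),
                          formula = character(), mz = numeric(),
                          polarity = character(), ms_level = integer(),
                          adduct = character()))
  }
  adduct <- if (polarity == "+") {
    .class_rule(ann$lipid_class)$base_adduct
  } else {
    "[M-H]-"
  }
  rows <- purrr::pmap(cl, function(chain_index, p, u, mass_degenerate) {
    ald <- aldehyde_formula(ann, p, u)
    out <- tibble::tibble(
      role = "ozesi_aldehyde", p = p, u = u,
      formula = format(ald),
      mz = adduct_mz(ald, adduct)
    )
    if (include_criegee) {
      cri <- el_add(ald, el(O = 1))
      out <- dplyr::bind_rows(out, tibble::tibble(
        role = "ozesi_criegee", p = p, u = u,
        formula = format(cri),
        mz = adduct_mz(cri, adduct)
      ))
    }
    out
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(polarity = polarity, ms_level = 1L, adduct = adduct)
  # keep one representative per (role, m/z) within 1e-6 Da
  out |>
    dplyr::arrange(.data$role, .data$mz, .data$p) |>
    dplyr::group_by(.data$role) |>
    dplyr::filter(c(TRUE, diff(.data$mz) > 1e-6)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p, .data$role)
}

#' The nitrogen-oxide derivatization (OzNOx) precursor adduct
#'
#' All C=C of one species converge to a single precursor m/z: positive
#' mode `[M+NO4-H]+` (ammonium-adduct classes PG/PI/LPG/FA gain an
#' additional NH3 by default), negative mode `[M+N2O7]-`.
#'
#' @param annotation Species with at least one C=C.
#' @param polarity `"+"` or `"-"`.
#' @param ammoniate Add NH3 for ammonium-adduct classes (default TRUE).
#' @param negative_adduct Negative-mode adduct name (default
#'   `"[M+N2O7]-"`; `"[M+N2O7-H]-"` also registered).
#' @return One-row tibble: `role`, `formula`, `mz`, `polarity`,
#'   `ms_level`, `adduct`.
#' @export
oznox_precursor <- function(annotation, polarity = c("+", "-"),
                            ammoniate = TRUE,
                            negative_adduct = "[M+N2O7]-") {
  ann <- .as_lipid(annotation)
  polarity <- match.arg(polarity)
  if (total_double_bonds(ann) < 1) {
    stop("saturated species form no ozonide-derived adduct: ",
         format(ann), call. = FALSE)
  }
  base <- composition(ann)
  rule <- .class_rule(ann$lipid_class)
  if (polarity == "+") {
    adduct <- if (ammoniate && rule$base_adduct == "[M+NH4]+") {
      "[M+NO4-H+NH3]+"
    } else {
      "[M+NO4-H]+"
    }
  } else {
    adduct <- negative_adduct
  }
  tibble::tibble(
    role = if (polarity == "+") "oznox_precursor" else "oznox_precursor_negative",
    formula = format(base),
    mz = adduct_mz(base, adduct),
    polarity = polarity,
    ms_level = 1L,
    adduct = adduct
  )
}

# role -> ion m/z from the neutral aldehyde formula
.role_mz <- function(role, ald, headgroup_loss) {
  switch(
    role,
    ms2_aldehyde = adduct_mz(ald, "[M+H]+"),
    ms2_aldehyde_NH4 = adduct_mz(ald, "[M+NH4]+"),
    ms2_aldehyde_minus_CHO =
      adduct_mz(el_sub(ald, el(C = 1, H = 1, O = 1)), "[M+H]+"),
    ms2_aldehyde_minus_H2O =
      adduct_mz(el_sub(ald, el(H = 2, O = 1)), "[M+H]+"),
    ms2_headgroup_lost =
      adduct_mz(el_sub(ald, parse_formula(headgroup_loss)), "[M+H]+"),
    ms2_headgroup_lost_minus_CHO =
      adduct_mz(el_sub(el_sub(ald, parse_formula(headgroup_loss)),
                       el(C = 1, H = 1, O = 1)), "[M+H]+"),
    stop("unknown MS2 role: ", role, call. = FALSE)
  )
}

.role_formula <- function(role, ald, headgroup_loss) {
  f <- switch(
    role,
    ms2_aldehyde = ald,
    ms2_aldehyde_NH4 = el_add(ald, el(N = 1, H = 3)),
    ms2_aldehyde_minus_CHO = el_sub(ald, el(C = 1, H = 1, O = 1)),
    ms2_aldehyde_minus_H2O = el_sub(ald, el(H = 2, O = 1)),
    ms2_headgroup_lost = el_sub(ald, parse_formula(headgroup_loss)),
    ms2_headgroup_lost_minus_CHO =
      el_sub(el_sub(ald, parse_formula(headgroup_loss)),
             el(C = 1, H = 1, O = 1))
  )
  format(f)
}

.class_ms2_roles <- function(rule) {
  roles <- rule$roles[[1]]
  if (isTRUE(rule$emit_headgroup_retained_pairs)) {
    roles <- c(roles, "ms2_aldehyde", "ms2_aldehyde_minus_CHO")
  }
  roles
}

#' MS2 roles m/z for one cleavage of one species
#' @keywords internal
.ms2_for_cleavage <- function(ann, p, u, rule) {
  ald <- aldehyde_formula(ann, p, u)
  roles <- .class_ms2_roles(rule)
  tibble::tibble(
    role = roles,
    p = p, u = u,
    formula = unname(vapply(roles, .role_formula, character(1), ald = ald,
                            headgroup_loss = rule$headgroup_loss)),
    mz = unname(vapply(roles, .role_mz, numeric(1), ald = ald,
                       headgroup_loss = rule$headgroup_loss))
  )
}

#' Theoretical class-specific MS2 diagnostic ions
#'
#' For each cleavage event, emits the diagnostic roles of the class rule
#' (see [class_rules()]). All products are positive-mode MS2 ions of the
#' derivatized precursor; every row carries its generating cleavage.
#'
#' @param annotation Position-resolved species.
#' @param rules Rule table, defaults to [class_rules()].
#' @return Tibble: `role`, `chain_index`, `p`, `u`, `mass_degenerate`,
#'   `formula`, `mz`, `polarity`, `ms_level` (= 2).
#' @examples
#' oznox_ms2_products("FA 18:1(n-9)") # 3 ions
#' @export
oznox_ms2_products <- function(annotation, rules = class_rules()) {
  ann <- .as_lipid(annotation)
  rule <- .class_rule(ann$lipid_class, rules)
  cl <- enumerate_cleavages(ann)
  if (nrow(cl) == 0) {
    return(tibble::tibble(role = character(), chain_index = integer(),
                          p = integer(), u = integer(),
                          mass_degenerate = logical(), formula = character(),
                          mz = numeric(), polarity = character(),
                          ms_level = integer()))
  }
  rows <- purrr::pmap(cl, function(chain_index, p, u, mass_degenerate) {
    .ms2_for_cleavage(ann, p, u, rule) |>
      dplyr::mutate(chain_index = chain_index,
                    mass_degenerate = mass_degenerate)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(polarity = "+", ms_level = 2L) |>
    dplyr::select("role", "chain_index", "p", "u", "mass_degenerate",
                  "formula", "mz", "polarity", "ms_level") |>
    dplyr::arrange(.data$chain_index, .data$p, .data$role)
}

#' All theoretical products for a table of annotations
#'
#' Tidy wrapper combining [ozesi_products()], [oznox_precursor()] and
#' [oznox_ms2_products()] over a parsed annotation tibble.
#'
#' @param annotations Tibble from [parse_annotations()] (or input it
#'   accepts). Saturated and position-unresolved species contribute only
#'   what is defined for them.
#' @param polarity Polarity for the MS1 ozonolysis products.
#' @return Tibble with an `annotation` column prepended to the product
#'   columns.
#' @export
theoretical_products <- function(annotations, polarity = "+") {
  if (!is.data.frame(annotations)) {
    annotations <- parse_annotations(annotations)
  }
  purrr::map2_dfr(annotations$lipid, annotations$annotation, function(ann, lab) {
    parts <- list()
    if (total_double_bonds(ann) > 0) {
      parts$prec <- oznox_precursor(ann, "+") |>
        dplyr::mutate(chain_index = NA_integer_, p = NA_integer_,
                      u = NA_integer_)
      if (positions_complete(ann)) {
        parts$ms1 <- ozesi_products(ann, polarity) |>
          dplyr::mutate(chain_index = NA_integer_)
        parts$ms2 <- oznox_ms2_products(ann) |>
          dplyr::mutate(adduct = NA_character_)
      }
    }
    if (length(parts) == 0) return(NULL)
    dplyr::bind_rows(parts) |>
      dplyr::mutate(annotation = lab, .before = 1)
  })
}
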