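# Lipid shorthand parsing.
#
# Supported grammar (whitespace-separated class token and chain block):
#   [dN-]CLASS c1:d1[(n-a,b,...)][SEP c2:d2[(n-...)]]
# where CLASS is one of PC PE PG PI PS PA LPC LPE LPG FA, SEP is "/"
# (sn-resolved) or "_" (unresolved), and "(n-a,b,...)" lists double-bond
# positions counted from the methyl terminus of the preceding chain.
# A single chain token on a diacyl class ("PC 37:3") is a sum composition.

.lipid_classes <- c("PC", "PE", "PG", "PI", "PS", "PA",
                    "LPC", "LPE", "LPG", "FA")
.diacyl_classes <- c("PC", "PE", "PG", "PI", "PS", "PA")
.monoacyl_classes <- c("LPC", "LPE", "LPG", "FA")

#' Default legality bounds for methyl-terminal double-bond positions
#'
#' A C=C at position n-p sits between carbons p and p+1 from the methyl
#' terminus; p must be at least `min_n` (default 2), at most
#' `carbons - 2`, and successive positions on one chain must differ by at
#' least `min_spacing` (default 2, which admits conjugated and
#' non-methylene-interrupted patterns).
#'
#' @return Named list with `min_n`, `min_spacing`.
#' @export
position_rules <- function() {
  list(min_n = 2L, min_spacing = 2L)
}

.check_chain <- function(carbons, double_bonds, n_positions,
                         rules = position_rules(), where = "") {
  if (carbons < 2) stop("chain must have >= 2 carbons", call. = FALSE)
  if (double_bonds < 0 || double_bonds > floor((carbons - 2) / 2)) {
    stop("impossible double-bond count ", double_bonds, " for ",
         carbons, "-carbon chain", where, call. = FALSE)
  }
  if (length(n_positions) > 0) {
    if (length(n_positions) != double_bonds) {
      stop("position list (", paste(n_positions, collapse = ","),
           ") inconsistent with double-bond count ", double_bonds,
           where, call. = FALSE)
    }
    if (is.unsorted(n_positions, strictly = TRUE)) {
      stop("n-positions must be strictly increasing", where, call. = FALSE)
    }
    if (min(n_positions) < rules$min_n || max(n_positions) > carbons - 2) {
      stop("n-position out of range [", rules$min_n, ", carbons-2]",
           where, call. = FALSE)
    }
    if (double_bonds > 1 && any(diff(n_positions) < rules$min_spacing)) {
      stop("n-positions closer than minimum spacing ", rules$min_spacing,
           where, call. = FALSE)
    }
  }
  list(carbons = as.integer(carbons),
       double_bonds = as.integer(double_bonds),
       n_positions = as.integer(n_positions))
}

#' Parse one lipid shorthand annotation
#'
#' @param text Shorthand string, e.g. `"PC 16:0/22:6(n-3,6,9,12,15,18)"`,
#'   `"FA 18:1(n-9)"`, `"PE 16:1(n-7)_18:1(n-7)"`, `"PC 37:3"`,
#'   `"d5-PC 17:0/22:4(n-6,9,12,15)"`.
#' @param retention_time Optional retention time in minutes.
#' @param rules Position legality bounds, see [position_rules()].
#' @return A `lipid_annotation` object: list with `lipid_class`, `chains`
#'   (each a list with `carbons`, `double_bonds`, `n_positions`),
#'   `sum_composition_only`, `chain_linkage_resolved`, `sn_resolved`,
#'   `deuterium_count`, `retention_time`.
#' @examples
#' parse_annotation("PC 16:0/22:6(n-3,6,9,12,15,18)")
#' parse_annotation("FA 18:1(n-9)")
#' @export
parse_annotation <- function(text, retention_time = NA_real_,
                             rules = position_rules()) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- trimws(text)
  if (!nzchar(raw)) stop("empty annotation", call. = FALSE)

  deut <- 0L
  m <- stringr::str_match(raw, "^d(\\d+)-(.*)$")
  if (!is.na(m[1, 1])) {
    deut <- as.integer(m[1, 2])
    raw <- m[1, 3]
  }

  m <- stringr::str_match(raw, "^([A-Za-z]+)\\s+(\\S.*)$")
  if (is.na(m[1, 1])) stop("malformed annotation: ", text, call. = FALSE)
  cls <- toupper(m[1, 2])
  if (!cls %in% .lipid_classes) {
    stop("unknown lipid class token: ", m[1, 2], call. = FALSE)
  }
  chain_block <- gsub("\\s+", "", m[1, 3])

  sn_resolved <- grepl("/", chain_block, fixed = TRUE)
  if (sn_resolved && grepl("_", chain_block, fixed = TRUE)) {
    stop("mixed chain separators in: ", text, call. = FALSE)
  }
  toks <- strsplit(chain_block, "[/_]")[[1]]
  if (length(toks) == 0 || any(!nzchar(toks)) ||
      grepl("[/_]$", chain_block)) {
    stop("malformed chain block: ", text, call. = FALSE)
  }

  chain_re <- "^(\\d+):(\\d+)(\\(n-(\\d+(,\\d+)*)\\))?$"
  chains <- lapply(seq_along(toks), function(i) {
    cm <- stringr::str_match(toks[i], chain_re)
    if (is.na(cm[1, 1])) {
      stop("chain token not matching C:D pattern: '", toks[i], "'",
           call. = FALSE)
    }
    pos <- if (is.na(cm[1, 4])) integer(0) else
      as.integer(strsplit(cm[1, 5], ",")[[1]])
    .check_chain(as.integer(cm[1, 2]), as.integer(cm[1, 3]), pos,
                 rules, where = paste0(" in '", text, "'"))
  })

  n_expected <- if (cls %in% .diacyl_classes) 2L else 1L
  sum_only <- FALSE
  if (length(chains) == 1 && n_expected == 2L) {
    sum_only <- TRUE
  } else if (length(chains) != n_expected) {
    stop(cls, " expects ", n_expected, " chain(s), got ", length(chains),
         call. = FALSE)
  }
  if (sum_only && length(chains[[1]]$n_positions) > 0 && n_expected == 2L) {
    # positions on a sum composition are carried but chain-unattributed
    chains[[1]]$n_positions <- chains[[1]]$n_positions
  }

  structure(
    list(
      lipid_class = cls,
      chains = chains,
      sum_composition_only = sum_only,
      chain_linkage_resolved = !sum_only,
      sn_resolved = sn_resolved && !sum_only,
      deuterium_count = deut,
      retention_time = as.numeric(retention_time)
    ),
    class = "lipid_annotation"
  )
}

#' @export
format.lipid_annotation <- function(x, ...) {
  fmt_chain <- function(ch) {
    pos <- if (length(ch$n_positions) > 0) {
      paste0("(n-", paste(ch$n_positions, collapse = ","), ")")
    } else ""
    paste0(ch$carbons, ":", ch$double_bonds, pos)
  }
  sep <- if (x$sn_resolved) "/" else "_"
  chains <- paste(vapply(x$chains, fmt_chain, character(1)), collapse = sep)
  lab <- if (x$deuterium_count > 0) paste0("d", x$deuterium_count, "-") else ""
  paste0(lab, x$lipid_class, " ", chains)
}

#' @export
print.lipid_annotation <- function(x, ...) {
  cat("<lipid_annotation> ", format(x), sep = "")
  if (x$sum_composition_only) cat("  [sum composition]")
  if (is.finite(x$retention_time)) cat("  RT ", x$retention_time, " min", sep = "")
  cat("\n")
  invisible(x)
}

#' Total carbons / double bonds of an annotation
#' @param annotation `lipid_annotation`.
#' @return Integer.
#' @keywords internal
total_carbons <- function(annotation) {
  sum(vapply(annotation$chains, `[[`, integer(1), "carbons"))
}

#' @rdname total_carbons
#' @keywords internal
total_double_bonds <- function(annotation) {
  sum(vapply(annotation$chains, `[[`, integer(1), "double_bonds"))
}

#' Are all double-bond positions specified?
#' @param annotation `lipid_annotation`.
#' @return Logical scalar.
#' @export
positions_complete <- function(annotation) {
  all(vapply(annotation$chains, function(ch) {
    length(ch$n_positions) == ch$double_bonds
  }, logical(1)))
}

#' Parse a vector or table of annotations into a tibble
#'
#' The tidy entry point: accepts a character vector or a data frame with
#' an `annotation` column (optionally `retention_time_min` and `adduct`)
#' and returns one row per species with the parsed object in a list
#' column.
#'
#' @param x Character vector or data frame.
#' @param rules Position legality bounds.
#' @return Tibble with columns `annotation` (canonical string),
#'   `lipid_class`, `total_carbons`, `total_double_bonds`,
#'   `positions_complete`, `sum_composition_only`, `deuterium_count`,
#'   `retention_time`, `adduct` (NA unless supplied), `lipid` (list of
#'   `lipid_annotation`).
#' @export
parse_annotations <- function(x, rules = position_rules()) {
  if (is.character(x)) {
    x <- tibble::tibble(annotation = x)
  }
  stopifnot(is.data.frame(x), "annotation" %in% names(x))
  rt <- if ("retention_time_min" %in% names(x)) {
    as.numeric(x$retention_time_min)
  } else {
    rep(NA_real_, nrow(x))
  }
  add <- if ("adduct" %in% names(x)) as.character(x$adduct) else
    rep(NA_character_, nrow(x))
  lipids <- purrr::map2(x$annotation, rt,
                        ~ parse_annotation(.x, retention_time = .y,
                                           rules = rules))
  tibble::tibble(
    annotation = vapply(lipids, format, character(1)),
    lipid_class = vapply(lipids, `[[`, character(1), "lipid_class"),
    total_carbons = vapply(lipids, total_carbons, integer(1)),
    total_double_bonds = vapply(lipids, total_double_bonds, integer(1)),
    positions_complete = vapply(lipids, positions_complete, logical(1)),
    sum_composition_only = vapply(lipids, `[[`, logical(1),
                                  "sum_composition_only"),
    deuterium_count = vapply(lipids, `[[`, integer(1), "deuterium_count"),
    retention_time = rt,
    adduct = add,
    lipid = lipids
  )
}

#' Read an annotation table from TSV/CSV
#'
#' Expects columns `annotation` and optionally `retention_time_min`,
#' `adduct`; the delimiter is inferred from the file extension
#' (`.csv` means comma, anything else tab).
#'
#' @param path File path.
#' @inheritParams parse_annotations
#' @return Tibble as from [parse_annotations()].
#' @export
read_annotations <- function(path, rules = position_rules()) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  parse_annotations(df, rules = rules)
}

.as_lipid <- function(x) {
  if (inherits(x, "lipid_annotation")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_annotation(x))
  stop("expected a lipid_annotation or a shorthand string", call. = FALSE)
}
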