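# Independent oracles used across tests.

# Elemental-sum mass oracle with its own isotope table (coded separately
# from the package's element_masses).
oracle_mass <- function(formula_string) {
  tab <- c(C = 12.0, H = 1.0078250319, D = 2.0141017780,
           N = 14.0030740052, O = 15.9949146221, P = 30.97376151)
  m <- gregexpr("([A-Z])([0-9]*)", formula_string)[[1]]
  toks <- regmatches(formula_string, list(m))[[1]]
  total <- 0
  for (t in toks) {
    sym <- substr(t, 1, 1)
    n <- sub("^[A-Z]", "", t)
    n <- if (n == "") 1 else as.integer(n)
    total <- total + tab[[sym]] * n
  }
  total
}

# Brute-force regioisomer oracle: generate every legal position pattern
# per chain, keep combinations whose full expected-event multiset lies
# within the detected set. Returns sorted candidate signatures
# ("p/u;p/u;...") over distinct events.
oracle_patterns <- function(carbons, d, min_n = 2, spacing = 2) {
  pats <- list()
  gen <- function(prefix, k) {
    if (k > d) {
      pats[[length(pats) + 1]] <<- prefix
      return(invisible())
    }
    lo <- if (length(prefix) == 0) min_n else
      max(min_n, prefix[length(prefix)] + spacing)
    hi <- carbons - 2 - spacing * (d - k)
    if (lo <= hi) for (p in lo:hi) gen(c(prefix, p), k + 1)
  }
  gen(integer(0), 1)
  pats
}

oracle_candidates <- function(chains, detected, min_n = 2, spacing = 2) {
  det_keys <- paste(detected$p, detected$u, sep = "/")
  per_chain <- lapply(chains, function(ch) {
    if (ch$d == 0) return(list(integer(0)))
    Filter(function(pos) {
      all(paste(pos, seq_along(pos) - 1, sep = "/") %in% det_keys)
    }, oracle_patterns(ch$c, ch$d, min_n, spacing))
  })
  if (any(lengths(per_chain) == 0)) return(character(0))
  idx <- expand.grid(lapply(per_chain, seq_along))
  sigs <- apply(idx, 1, function(row) {
    ev <- do.call(rbind, lapply(seq_along(row), function(j) {
      pos <- per_chain[[j]][[row[j]]]
      if (length(pos) == 0) return(NULL)
      cbind(p = pos, u = seq_along(pos) - 1)
    }))
    ev <- ev[order(ev[, "u"], ev[, "p"]), , drop = FALSE]
    paste(ev[, "p"], ev[, "u"], sep = "/", collapse = ";")
  })
  sort(unique(sigs))
}

# Signatures produced by the package for direct comparison.
package_signatures <- function(annotation, detected, ...) {
  sort(unique(enumerate_candidates(annotation, detected, ...)$signature))
}

# Hand-built detected-event table (noise-free, equal per-scan intensity)
# for scoring fixtures: `events` is a tibble with p, u, intensity;
# every event is present and qualifying in `n_scans` scans.
fake_detected <- function(events, n_scans = 3) {
  scans <- lapply(seq_len(nrow(events)), function(i) {
    tibble::tibble(scan_id = seq_len(n_scans), rt = seq_len(n_scans) / 10,
                   n_roles = 2L, intensity = events$intensity[i],
                   qualifies = TRUE)
  })
  tibble::tibble(p = as.integer(events$p), u = as.integer(events$u),
                 n_scans = n_scans,
                 total_intensity = events$intensity * n_scans,
                 roles_matched = 2L, scans = scans)
}

# Hand-built candidate rows (bypassing enumeration) for scoring tests.
fake_candidates <- function(expected_list, labels = NULL) {
  if (is.null(labels)) {
    labels <- paste0("cand", seq_along(expected_list))
  }
  tibble::tibble(
    candidate = labels,
    positions = lapply(expected_list, function(ev) list(ev$p)),
    expected = lapply(expected_list, function(ev) {
      tibble::tibble(p = as.integer(ev$p), u = as.integer(ev$u),
                     degenerate = FALSE)
    }),
    signature = vapply(expected_list, function(ev) {
      paste(ev$p, ev$u, sep = "/", collapse = ";")
    }, character(1)),
    n_events = vapply(expected_list, nrow, integer(1)),
    ambiguous_chains = FALSE,
    over_cap = FALSE
  )
}
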