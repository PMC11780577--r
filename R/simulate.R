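# Seeded synthetic LC-MS run generator with known regioisomer ground
# truth. Emulates the acquisition scheme of the source-derivatization
# workflow: full-scan MS1 (precursor base adduct, the nitrogen-oxide
# derivatization adduct at a configurable ~10% yield, and in-source
# ozonolysis aldehyde/Criegee products) followed by scheduled PRM MS2
# scans of each derivatized precursor containing the class-rule
# diagnostic ions. Chromatographic peaks are Gaussian in RT; optional
# multiplicative log-normal intensity noise, Gaussian ppm mass jitter,
# and additive uniform baseline.

#' Specify a synthetic run scenario
#'
#' @param species Tibble/data frame with columns `annotation` (shorthand
#'   with complete n-positions), `amount` (relative amount, > 0), `rt`
#'   (apex, minutes), `sigma` (chromatographic SD, minutes).
#' @param oznox_yield Derivatization adduct yield relative to the
#'   precursor ion (default 0.10).
#' @param ozesi_yield MS1 ozonolysis product yield per cleavage
#'   (default 0.05).
#' @param decline Per-position response decline factor: the ion of the
#'   r-th lowest cleavage position is scaled by `decline^(r-1)`
#'   (default 1 = position independence).
#' @param ppm_sigma Gaussian m/z jitter SD in ppm (default 0).
#' @param noise Multiplicative log-normal intensity noise SD on the log
#'   scale (default 0; 0.05 is about 5% noise).
#' @param baseline Additive uniform baseline amplitude (default 0).
#' @param baseline_peaks Random baseline peaks per scan (default 0).
#' @param scan_interval MS1 scan spacing in minutes (default 0.02).
#' @param rt_span Length-2 RT span in minutes; default covers every
#'   species apex +/- 5 sigma.
#' @param isolation_width PRM isolation width in Th (default 1).
#' @param intensity_scale Intensity of one amount unit at apex
#'   (default 1e6).
#' @param seed Integer seed; identical seeds give identical runs.
#' @return List of class `oznox_scenario`.
#' @export
scenario_spec <- function(species, oznox_yield = 0.10, ozesi_yield = 0.05,
                          decline = 1, ppm_sigma = 0, noise = 0,
                          baseline = 0, baseline_peaks = 0,
                          scan_interval = 0.02, rt_span = NULL,
                          isolation_width = 1, intensity_scale = 1e6,
                          seed = 1L) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("annotation", "amount", "rt", "sigma") %in%
                  names(species)))
  if (any(species$amount <= 0)) stop("amounts must be > 0", call. = FALSE)
  if (any(species$sigma <= 0)) stop("sigmas must be > 0", call. = FALSE)
  if (oznox_yield <= 0 || oznox_yield > 1) {
    stop("oznox_yield must be in (0, 1]", call. = FALSE)
  }
  if (is.null(rt_span)) {
    rt_span <- c(min(species$rt - 5 * species$sigma),
                 max(species$rt + 5 * species$sigma))
  }
  structure(list(species = species, oznox_yield = oznox_yield,
                 ozesi_yield = ozesi_yield, decline = decline,
                 ppm_sigma = ppm_sigma, noise = noise,
                 baseline = baseline, baseline_peaks = baseline_peaks,
                 scan_interval = scan_interval, rt_span = rt_span,
                 isolation_width = isolation_width,
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "oznox_scenario")
}

#' Simulate a synthetic LC-MS run
#'
#' @param spec `oznox_scenario` from [scenario_spec()] or
#'   [preset_scenarios()].
#' @return List of class `oznox_sim`: `run` (an [ms_run()]), `ledger`
#'   (tibble mapping every emitted theoretical peak to species, role and
#'   cleavage), `truth` (per-annotation true isomer percentages),
#'   `spec`.
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "oznox_scenario"))
  sp <- spec$species
  parsed <- lapply(sp$annotation, parse_annotation)
  for (ann in parsed) {
    if (!positions_complete(ann)) {
      stop("scenario species must have complete n-positions: ",
           format(ann), call. = FALSE)
    }
  }

  # theoretical peak templates per species
  templates <- purrr::imap_dfr(parsed, function(ann, i) {
    base_adduct <- .class_rule(ann$lipid_class)$base_adduct
    prec <- tibble::tibble(
      role = "precursor", p = NA_integer_, u = NA_integer_,
      mz = adduct_mz(composition(ann), base_adduct),
      rel = 1, ms_level = 1L
    )
    oz <- oznox_precursor(ann, "+")
    oznox <- tibble::tibble(role = "oznox_precursor", p = NA_integer_,
                            u = NA_integer_, mz = oz$mz,
                            rel = spec$oznox_yield, ms_level = 1L)
    cl <- enumerate_cleavages(ann) |>
      dplyr::distinct(.data$p, .data$u, .keep_all = TRUE) |>
      dplyr::arrange(.data$p)
    rank_p <- seq_len(nrow(cl))
    ms1 <- purrr::pmap_dfr(
      cbind(cl, rank = rank_p),
      function(chain_index, p, u, mass_degenerate, rank) {
        ald <- aldehyde_formula(ann, p, u)
        tibble::tibble(
          role = c("ozesi_aldehyde", "ozesi_criegee"),
          p = p, u = u,
          mz = c(adduct_mz(ald, base_adduct),
                 adduct_mz(el_add(ald, el(O = 1)), base_adduct)),
          rel = spec$ozesi_yield * spec$decline^(rank - 1),
          ms_level = 1L
        )
      })
    rule <- .class_rule(ann$lipid_class)
    ms2 <- purrr::pmap_dfr(
      cbind(cl, rank = rank_p),
      function(chain_index, p, u, mass_degenerate, rank) {
        ions <- .ms2_for_cleavage(ann, p, u, rule)
        tibble::tibble(
          role = ions$role, p = p, u = u, mz = ions$mz,
          rel = spec$oznox_yield * spec$decline^(rank - 1) *
            (if (mass_degenerate) 2 else 1),
          ms_level = 2L
        )
      })
    dplyr::bind_rows(prec, oznox, ms1, ms2) |>
      dplyr::mutate(species_index = i, annotation = format(ann),
                    precursor_mz = oz$mz)
  })

  grid <- seq(spec$rt_span[1], spec$rt_span[2], by = spec$scan_interval)
  gauss <- function(t, i) {
    sp$amount[i] * spec$intensity_scale *
      exp(-(t - sp$rt[i])^2 / (2 * sp$sigma[i]^2))
  }

  # PRM targets: one per distinct derivatized precursor m/z
  prm <- templates |>
    dplyr::distinct(.data$species_index, .data$precursor_mz) |>
    dplyr::mutate(group = match(round(.data$precursor_mz, 4),
                                unique(round(.data$precursor_mz, 4))))
  prm_groups <- prm |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(precursor_mz = dplyr::first(.data$precursor_mz),
                     members = list(.data$species_index),
                     .groups = "drop")
  prm_groups$rt_lo <- vapply(prm_groups$members, function(m) {
    min(sp$rt[m] - 4 * sp$sigma[m])
  }, numeric(1))
  prm_groups$rt_hi <- vapply(prm_groups$members, function(m) {
    max(sp$rt[m] + 4 * sp$sigma[m])
  }, numeric(1))

  tmpl1 <- templates[templates$ms_level == 1L, ]
  tmpl2 <- templates[templates$ms_level == 2L, ]

  withr::with_seed(spec$seed, {
    scans <- list(); peaks <- list(); sid <- 0L
    for (t in grid) {
      # MS1 scan
      sid <- sid + 1L
      amp <- vapply(seq_len(nrow(sp)), function(i) gauss(t, i), numeric(1))
      ints <- tmpl1$rel * amp[tmpl1$species_index]
      keep <- ints > spec$intensity_scale * 1e-9
      mzv <- tmpl1$mz[keep]; iv <- ints[keep]
      scans[[sid]] <- tibble::tibble(scan_id = sid, ms_level = 1L, rt = t,
                                     polarity = "+",
                                     precursor_mz = NA_real_,
                                     isolation_width = NA_real_)
      peaks[[sid]] <- .noisy_peaks(mzv, iv, spec)
      # PRM MS2 scans
      for (g in seq_len(nrow(prm_groups))) {
        if (t < prm_groups$rt_lo[g] || t >= prm_groups$rt_hi[g]) next
        members <- prm_groups$members[[g]]
        rows <- tmpl2[tmpl2$species_index %in% members, ]
        ints <- rows$rel * amp[rows$species_index]
        keep <- ints > spec$intensity_scale * 1e-9
        if (!any(keep)) next
        sid <- sid + 1L
        scans[[sid]] <- tibble::tibble(
          scan_id = sid, ms_level = 2L, rt = t, polarity = "+",
          precursor_mz = prm_groups$precursor_mz[g],
          isolation_width = spec$isolation_width)
        peaks[[sid]] <- .noisy_peaks(rows$mz[keep], ints[keep], spec)
      }
    }
    peaks <- purrr::imap(peaks, function(p, i) {
      if (nrow(p) == 0) return(p)
      dplyr::mutate(p, scan_id = i, .before = 1)
    })
    run <- ms_run(dplyr::bind_rows(scans), dplyr::bind_rows(peaks))
  })

  truth <- sp |>
    dplyr::mutate(annotation = vapply(parsed, format, character(1))) |>
    dplyr::group_by(precursor_mz = round(vapply(parsed, function(a) {
      oznox_precursor(a, "+")$mz
    }, numeric(1)), 4)) |>
    dplyr::mutate(true_pct = 100 * .data$amount / sum(.data$amount)) |>
    dplyr::ungroup() |>
    dplyr::select("annotation", "amount", "rt", "sigma", "true_pct")

  structure(list(run = run,
                 ledger = dplyr::select(templates, "annotation", "role",
                                        "p", "u", "mz", "rel", "ms_level",
                                        "precursor_mz"),
                 truth = truth, spec = spec),
            class = "oznox_sim")
}

# apply ppm jitter, multiplicative noise, baseline; merge into a peak
# tibble sorted by m/z
.noisy_peaks <- function(mz, intensity, spec) {
  n <- length(mz)
  if (n > 0) {
    if (spec$ppm_sigma > 0) {
      mz <- mz * (1 + stats::rnorm(n, 0, spec$ppm_sigma) * 1e-6)
    }
    if (spec$noise > 0) {
      intensity <- intensity * exp(stats::rnorm(n, 0, spec$noise))
    }
    if (spec$baseline > 0) {
      intensity <- intensity + stats::runif(n, 0, spec$baseline)
    }
  }
  if (spec$baseline_peaks > 0 && spec$baseline > 0) {
    mz <- c(mz, stats::runif(spec$baseline_peaks, 100, 1000))
    intensity <- c(intensity,
                   stats::runif(spec$baseline_peaks, 0, spec$baseline))
  }
  tibble::tibble(mz = mz, intensity = intensity) |>
    dplyr::arrange(mz)
}

#' @export
print.oznox_sim <- function(x, ...) {
  cat("<oznox_sim> ", nrow(x$spec$species), " species, seed ",
      x$spec$seed, "\n", sep = "")
  print(x$run)
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Named scenarios mirroring the study's qualitative situations:
#' \describe{
#'   \item{pc_22_6}{PC 16:0/22:6(n-3,6,9,12,15,18), the predominant
#'     plasma regioisomer; six diagnostic pairs.}
#'   \item{pe_pair}{PE 16:1(n-7)_18:1(n-7): two chains with the same
#'     n-position, mass-degenerate products.}
#'   \item{fa_16_1_seven_isomers}{FA 16:1 as seven coeluting isomers,
#'     n-7 dominant at 92.1%, n-9 at 6.9%, five minors sharing ~1%.}
#'   \item{lpc_coelution}{LPC 22:4(n-6,9,12,15) coeluting with
#'     LPC 18:1(n-9): the n-15 aldehyde of the former is
#'     formula-identical to the n-11 aldehyde of an LPC 18:1, creating
#'     a spurious MS1 feature that PRM MS2 resolves.}
#'   \item{lpc_18_1_mix}{LPC 18:1 as a 75/25 n-9/n-7 mixture, the
#'     parameter-recovery benchmark.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the scenario (default 1).
#' @param ... Overrides passed on to [scenario_spec()].
#' @return `oznox_scenario`.
#' @export
preset_scenarios <- function(name, seed = 1L, ...) {
  presets <- list(
    pc_22_6 = function() scenario_spec(
      tibble::tibble(annotation = "PC 16:0/22:6(n-3,6,9,12,15,18)",
                     amount = 1, rt = 12, sigma = 0.05),
      seed = seed, ...),
    pe_pair = function() scenario_spec(
      tibble::tibble(annotation = "PE 16:1(n-7)_18:1(n-7)",
                     amount = 1, rt = 14, sigma = 0.05),
      seed = seed, ...),
    fa_16_1_seven_isomers = function() scenario_spec(
      tibble::tibble(
        annotation = paste0("FA 16:1(n-", c(5, 6, 7, 9, 10, 11, 12), ")"),
        amount = c(0.2, 0.2, 92.1, 6.9, 0.2, 0.2, 0.2),
        rt = 8, sigma = 0.05),
      seed = seed, ...),
    lpc_coelution = function() scenario_spec(
      tibble::tibble(
        annotation = c("LPC 22:4(n-6,9,12,15)", "LPC 18:1(n-9)"),
        amount = c(1, 1), rt = c(10.00, 10.04), sigma = 0.05),
      seed = seed, ...),
    lpc_18_1_mix = function() scenario_spec(
      tibble::tibble(annotation = c("LPC 18:1(n-9)", "LPC 18:1(n-7)"),
                     amount = c(75, 25), rt = 10, sigma = 0.05),
      seed = seed, ...)
  )
  f <- presets[[name]]
  if (is.null(f)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  f()
}

#' Write simulator outputs to a directory
#'
#' Emits the run in both mzML (when mzR is installed) and the TSV
#' peak-list dialect, plus the peak ledger and ground-truth tables.
#'
#' @param sim `oznox_sim`.
#' @param dir Output directory (created if missing).
#' @param mzml Also write mzML (default TRUE when mzR is available).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, dir,
                      mzml = requireNamespace("mzR", quietly = TRUE)) {
  stopifnot(inherits(sim, "oznox_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    run_tsv = file.path(dir, "run.tsv"),
    ledger = file.path(dir, "ledger.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_run(sim$run, paths[["run_tsv"]])
  readr::write_tsv(sim$ledger, paths[["ledger"]], progress = FALSE)
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  if (mzml) {
    paths <- c(paths, run_mzml = file.path(dir, "run.mzML"))
    write_run(sim$run, paths[["run_mzml"]])
  }
  invisible(paths)
}
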