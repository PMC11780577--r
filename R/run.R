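# LC-MS run container and I/O (mzML via mzR; a TSV peak-list dialect for
# human-readable fixtures).
#
# An ms_run holds two tibbles: `scans` (scan_id, ms_level, rt [minutes],
# polarity, precursor_mz, isolation_width) and `peaks` (scan_id, mz,
# intensity), peaks sorted by m/z within each scan. RT intervals are
# half-open [start, end) everywhere.

#' Construct an LC-MS run object
#'
#' @param scans Tibble with columns `scan_id`, `ms_level`, `rt` (min),
#'   `polarity` ("+"/"-"), `precursor_mz` (NA for MS1),
#'   `isolation_width` (full width, NA for MS1).
#' @param peaks Tibble with columns `scan_id`, `mz`, `intensity`.
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(scans, peaks) {
  scans <- tibble::as_tibble(scans)
  peaks <- tibble::as_tibble(peaks)
  need_s <- c("scan_id", "ms_level", "rt", "polarity", "precursor_mz",
              "isolation_width")
  if (!all(need_s %in% names(scans))) {
    stop("scans must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("scan_id", "mz", "intensity") %in% names(peaks))) {
    stop("peaks must have columns scan_id, mz, intensity", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) stop("negative peak intensity", call. = FALSE)
  if (any(scans$ms_level == 2 & !is.finite(scans$precursor_mz))) {
    stop("MS2 scans must carry a precursor m/z", call. = FALSE)
  }
  peaks <- dplyr::arrange(peaks, .data$scan_id, .data$mz)
  structure(list(scans = dplyr::arrange(scans, .data$scan_id),
                 peaks = peaks),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  n1 <- sum(x$scans$ms_level == 1)
  n2 <- sum(x$scans$ms_level == 2)
  cat("<ms_run> ", n1, " MS1 + ", n2, " MS2 scans, ",
      nrow(x$peaks), " peaks, RT ",
      sprintf("%.2f-%.2f", min(x$scans$rt), max(x$scans$rt)), " min\n",
      sep = "")
  invisible(x)
}

#' Read an LC-MS run
#'
#' Dispatches on extension: `.mzML` through the mzR parser (centroided
#' spectra required; profile-mode data are rejected), anything else as
#' the TSV peak-list dialect with columns
#' `rt, ms_level, precursor_mz, mz, intensity` (precursor empty/NA for
#' MS1; rows belonging to one scan share `rt`, `ms_level`,
#' `precursor_mz`). RT is minutes in the TSV dialect and converted from
#' seconds when reading mzML.
#'
#' @param path File path.
#' @param default_isolation_width Isolation width assumed for MS2 scans
#'   that do not state one (TSV dialect), in Th. Default 1.
#' @return `ms_run`.
#' @export
read_run <- function(path, default_isolation_width = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    .read_run_mzml(path)
  } else {
    .read_run_tsv(path, default_isolation_width)
  }
}

.read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) {
    return(ms_run(
      tibble::tibble(scan_id = integer(), ms_level = integer(),
                     rt = numeric(), polarity = character(),
                     precursor_mz = numeric(), isolation_width = numeric()),
      tibble::tibble(scan_id = integer(), mz = numeric(),
                     intensity = numeric())
    ))
  }
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra are not supported; centroid the data first",
         call. = FALSE)
  }
  iso <- hdr$isolationWindowLowerOffset + hdr$isolationWindowUpperOffset
  scans <- tibble::tibble(
    scan_id = hdr$seqNum,
    ms_level = as.integer(hdr$msLevel),
    rt = hdr$retentionTime / 60,
    polarity = ifelse(is.na(hdr$polarity) | hdr$polarity >= 0, "+", "-"),
    precursor_mz = ifelse(hdr$msLevel >= 2, hdr$precursorMZ, NA_real_),
    isolation_width = ifelse(hdr$msLevel >= 2, iso, NA_real_)
  )
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- purrr::map2_dfr(pk, scans$scan_id, function(m, id) {
    tibble::tibble(scan_id = id, mz = m[, 1], intensity = m[, 2])
  })
  ms_run(scans, peaks)
}

.read_run_tsv <- function(path, default_isolation_width) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rt", "ms_level", "precursor_mz", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("peak-list TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(ms_run(
      tibble::tibble(scan_id = integer(), ms_level = integer(),
                     rt = numeric(), polarity = character(),
                     precursor_mz = numeric(), isolation_width = numeric()),
      tibble::tibble(scan_id = integer(), mz = numeric(),
                     intensity = numeric())
    ))
  }
  if (!"polarity" %in% names(df)) df$polarity <- "+"
  if (!"isolation_width" %in% names(df)) {
    df$isolation_width <- ifelse(df$ms_level >= 2,
                                 default_isolation_width, NA_real_)
  }
  key <- paste(df$rt, df$ms_level, df$precursor_mz)
  ids <- match(key, unique(key))
  scans <- df |>
    dplyr::mutate(scan_id = ids) |>
    dplyr::distinct(.data$scan_id, .data$ms_level, .data$rt,
                    .data$polarity, .data$precursor_mz,
                    .data$isolation_width)
  peaks <- tibble::tibble(scan_id = ids, mz = df$mz,
                          intensity = df$intensity)
  ms_run(scans, peaks)
}

#' Write an LC-MS run
#'
#' `.mzML` goes through mzR's writer; any other extension writes the TSV
#' peak-list dialect (one row per peak).
#'
#' @param run `ms_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    .write_run_mzml(run, path)
  } else {
    .write_run_tsv(run, path)
  }
  invisible(path)
}

.write_run_tsv <- function(run, path) {
  df <- dplyr::left_join(run$peaks, run$scans, by = "scan_id") |>
    dplyr::select("rt", "ms_level", "precursor_mz", "polarity",
                  "isolation_width", "mz", "intensity") |>
    dplyr::arrange(.data$rt, .data$ms_level, .data$precursor_mz, .data$mz)
  readr::write_tsv(df, path, progress = FALSE)
}

.write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  sc <- run$scans
  n <- nrow(sc)
  pk_list <- purrr::map(sc$scan_id, function(id) {
    p <- run$peaks[run$peaks$scan_id == id, ]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  counts <- vapply(pk_list, nrow, integer(1))
  tic <- vapply(pk_list, function(m) sum(m[, 2]), numeric(1))
  bp <- vapply(pk_list, function(m) {
    if (nrow(m) == 0) 0 else m[which.max(m[, 2]), 1]
  }, numeric(1))
  bpi <- vapply(pk_list, function(m) {
    if (nrow(m) == 0) 0 else max(m[, 2])
  }, numeric(1))
  lo <- vapply(pk_list, function(m) if (nrow(m) == 0) 0 else min(m[, 1]),
               numeric(1))
  hi <- vapply(pk_list, function(m) if (nrow(m) == 0) 0 else max(m[, 1]),
               numeric(1))
  ms2 <- sc$ms_level >= 2
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(sc$ms_level),
    polarity = ifelse(sc$polarity == "-", 0L, 1L),
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = sc$rt * 60,
    basePeakMZ = bp, basePeakIntensity = bpi,
    collisionEnergy = ifelse(ms2, 25, 0), ionisationEnergy = 0,
    lowMZ = lo, highMZ = hi,
    precursorScanNum = 0L,
    precursorMZ = ifelse(ms2, sc$precursor_mz, 0),
    precursorCharge = ifelse(ms2, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(ms2, sc$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(ms2, sc$isolation_width / 2,
                                        NA_real_),
    isolationWindowUpperOffset = ifelse(ms2, sc$isolation_width / 2,
                                        NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(object = pk_list, file = path, header = hdr)
}

#' Match the most intense in-tolerance peak
#'
#' Boundary-inclusive ppm window: a peak matches when
#' `|observed - target| / target * 1e6 <= tol_ppm`; of several matches
#' the most intense wins.
#'
#' @param peaks Tibble with `mz`, `intensity` (e.g. one scan's peaks).
#' @param target_mz Target m/z.
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return One-row tibble, or NULL when nothing matches.
#' @export
match_peak <- function(peaks, target_mz, tol_ppm) {
  stopifnot(tol_ppm > 0)
  hit <- peaks[abs(peaks$mz - target_mz) / target_mz * 1e6 <= tol_ppm, ]
  if (nrow(hit) == 0) return(NULL)
  hit[which.max(hit$intensity), ]
}

# Vectorized matcher: for each (scan_id, target) pair sum the
# in-tolerance intensity and keep the best single peak. Returns a tibble
# (scan_id, target_id, intensity, best_mz) with only non-zero matches.
.match_targets <- function(peaks, target_mz, tol_ppm) {
  out <- purrr::imap_dfr(target_mz, function(tz, i) {
    tol <- tz * tol_ppm * 1e-6
    hit <- peaks[peaks$mz >= tz - tol & peaks$mz <= tz + tol, ]
    if (nrow(hit) == 0) return(NULL)
    hit |>
      dplyr::group_by(.data$scan_id) |>
      dplyr::summarise(intensity = sum(.data$intensity),
                       best_mz = .data$mz[which.max(.data$intensity)],
                       .groups = "drop") |>
      dplyr::mutate(target_id = i)
  })
  out
}

#' Extract an ion chromatogram
#'
#' Per-scan summed intensity of peaks within a ppm window of the target
#' m/z, over MS1 scans (default) in an RT range. Scans with no matching
#' peak contribute zero. The apex is the RT of the maximum; the area is
#' trapezoidal over RT.
#'
#' @param run `ms_run`.
#' @param target_mz Target m/z.
#' @param tol_ppm Tolerance in ppm (default 5).
#' @param rt_range Length-2 numeric, half-open `[start, end)` in
#'   minutes; NULL means the full run.
#' @param ms_level Scan level to use (default 1).
#' @return Tibble of class `oznox_eic` with columns `rt`, `intensity`
#'   and attributes `target_mz`, `tol_ppm`, `apex_rt`, `area`.
#' @export
extract_eic <- function(run, target_mz, tol_ppm = 5, rt_range = NULL,
                        ms_level = 1) {
  stopifnot(inherits(run, "ms_run"))
  sc <- run$scans[run$scans$ms_level == ms_level, ]
  if (!is.null(rt_range)) {
    sc <- sc[sc$rt >= rt_range[1] & sc$rt < rt_range[2], ]
  }
  sc <- dplyr::arrange(sc, .data$rt)
  tol <- target_mz * tol_ppm * 1e-6
  pk <- run$peaks[run$peaks$scan_id %in% sc$scan_id &
                    run$peaks$mz >= target_mz - tol &
                    run$peaks$mz <= target_mz + tol, ]
  sums <- pk |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  out <- tibble::tibble(rt = sc$rt,
                        intensity = sums$intensity[match(sc$scan_id,
                                                         sums$scan_id)])
  out$intensity[is.na(out$intensity)] <- 0
  area <- if (nrow(out) > 1) {
    sum(diff(out$rt) * (utils::head(out$intensity, -1) +
                          utils::tail(out$intensity, -1)) / 2)
  } else 0
  apex <- if (nrow(out) > 0 && max(out$intensity) > 0) {
    out$rt[which.max(out$intensity)]
  } else NA_real_
  structure(out, class = c("oznox_eic", class(out)),
            target_mz = target_mz, tol_ppm = tol_ppm,
            apex_rt = apex, area = area)
}

#' Validate an annotation's retention time against a run
#'
#' Extracts the MS1 chromatogram of the species' base-adduct precursor
#' and passes when its apex lies within `expected_rt` +/- `window` and
#' the apex intensity exceeds `noise_floor`.
#'
#' @param run `ms_run`.
#' @param annotation Species (string or `lipid_annotation`).
#' @param expected_rt Expected RT in minutes; defaults to the
#'   annotation's own.
#' @param window Half-window in minutes (default 0.5).
#' @param tol_ppm MS1 tolerance (default 5).
#' @param noise_floor Minimum apex intensity (default 0).
#' @return One-row tibble: `annotation`, `pass`, `apex_rt`,
#'   `apex_intensity`.
#' @export
validate_rt <- function(run, annotation, expected_rt = NULL, window = 0.5,
                        tol_ppm = 5, noise_floor = 0) {
  ann <- .as_lipid(annotation)
  if (is.null(expected_rt)) expected_rt <- ann$retention_time
  if (!is.finite(expected_rt)) {
    stop("no expected retention time for ", format(ann), call. = FALSE)
  }
  mz <- adduct_mz(composition(ann), .class_rule(ann$lipid_class)$base_adduct)
  eic <- extract_eic(run, mz, tol_ppm = tol_ppm)
  apex <- attr(eic, "apex_rt")
  apex_int <- if (nrow(eic) > 0) max(eic$intensity) else 0
  pass <- is.finite(apex) && abs(apex - expected_rt) <= window &&
    apex_int > noise_floor
  tibble::tibble(annotation = format(ann), pass = pass,
                 apex_rt = apex, apex_intensity = apex_int)
}

#' Select the PRM scans belonging to a target
#'
#' An MS2 scan belongs to a target when its precursor lies within the
#' scan's isolation half-width of the target m/z and its RT falls in the
#' half-open target window; a scan eligible for several targets goes to
#' the nearest precursor.
#'
#' @param run `ms_run`.
#' @param targets Tibble from [build_prm_targets()].
#' @return `run$scans` rows (MS2 only) with an added `annotation`
#'   column.
#' @export
assign_prm_scans <- function(run, targets) {
  sc <- run$scans[run$scans$ms_level == 2, ]
  if (nrow(sc) == 0 || nrow(targets) == 0) {
    return(dplyr::mutate(sc[0, ], annotation = character(0)))
  }
  rows <- purrr::pmap_dfr(sc, function(...) {
    s <- list(...)
    half <- ifelse(is.finite(s$isolation_width), s$isolation_width / 2, 0.5)
    ok <- abs(targets$mz - s$precursor_mz) <= half &
      s$rt >= targets$rt_start_min & s$rt < targets$rt_end_min
    if (!any(ok)) return(NULL)
    cand <- targets[ok, ]
    pick <- which.min(abs(cand$mz - s$precursor_mz))
    tibble::as_tibble(s) |>
      dplyr::mutate(annotation = cand$annotation[pick])
  })
  rows
}
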