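# End-to-end workflow, configuration, and the command-line front end.

test_that("a clean single-isomer run is confirmed at 100%", {
  sim <- simulate_run(preset_scenarios("pc_22_6"))
  res <- annotate_run(sim$run, parse_annotations(tibble::tibble(
    annotation = "PC 16:0/22:6", retention_time_min = 12)))
  td <- tidy(res)
  expect_identical(td$candidate, "PC 16:0/22:6(n-3,6,9,12,15,18)")
  expect_equal(td$relative_abundance, 100)
  expect_identical(res$outcomes$outcome, "confirmed")
  g <- glance(res)
  expect_identical(g$n_confirmed, 1L)
})

test_that("coelution is resolved at MS2 while MS1 shows the spurious feature", {
  sim <- simulate_run(preset_scenarios("lpc_coelution"))
  anns <- parse_annotations(tibble::tibble(
    annotation = c("LPC 22:4", "LPC 18:1"),
    retention_time_min = c(10.0, 10.04)))
  res <- annotate_run(sim$run, anns)
  td <- tidy(res)
  # MS2: LPC 18:1 is pure n-9; any n-11 is pruned/absent
  lpc181 <- td[td$annotation == "LPC 18:1", ]
  expect_identical(lpc181$candidate, "LPC 18:1(n-9)")
  n11 <- td[grepl("n-11", td$candidate), ]
  expect_true(nrow(n11) == 0 || all(n11$relative_abundance < 1))
  # MS1: the aldehyde shared with LPC 22:4 cleaved at n-15 produces a
  # feature at the m/z where an LPC 18:1(n-11) aldehyde would sit
  spurious_mz <- ozesi_products("LPC 18:1(n-11)")
  spurious_mz <- spurious_mz$mz[spurious_mz$role == "ozesi_aldehyde"]
  eic <- extract_eic(sim$run, spurious_mz, tol_ppm = 5)
  expect_gt(attr(eic, "area"), 0)
})

test_that("a run without PRM scans reports not_detected without failing", {
  sim <- simulate_run(preset_scenarios("pc_22_6"))
  ms1_only <- ms_run(sim$run$scans[sim$run$scans$ms_level == 1, ],
                     sim$run$peaks[sim$run$peaks$scan_id %in%
                                     sim$run$scans$scan_id[
                                       sim$run$scans$ms_level == 1], ])
  res <- annotate_run(ms1_only, parse_annotations(tibble::tibble(
    annotation = "PC 16:0/22:6", retention_time_min = 12)))
  expect_identical(res$outcomes$outcome, "not_detected")
  expect_identical(nrow(tidy(res)), 0L)
})

test_that("configurations round-trip through JSON and reject junk", {
  cfg <- oznox_config(ms2_tol_ppm = 7.5, min_scans = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  writeLines('{"not_a_key": 1}', f)
  expect_error(read_config(f), "unknown config key")
  expect_error(oznox_config(ms1_tol_ppm = -1))
})

test_that("plot builders return ggplot objects", {
  sim <- simulate_run(preset_scenarios("lpc_18_1_mix"))
  eic <- extract_eic(sim$run, oznox_precursor("LPC 18:1(n-9)")$mz)
  expect_s3_class(autoplot(eic), "ggplot")
  res <- annotate_run(sim$run, parse_annotations(tibble::tibble(
    annotation = "LPC 18:1", retention_time_min = 10)))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_detected_events(res), "ggplot")
})

test_that("the command-line front end chains simulate, targets and annotate", {
  cli <- system.file("scripts", "oznox", package = "oznoxr")
  expect_true(nzchar(cli) && file.exists(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  withr::local_envvar(R_LIBS = libs, R_LIBS_USER = libs)
  run_cli <- function(...) {
    out <- suppressWarnings(
      system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
    st <- attr(out, "status")
    list(status = if (is.null(st)) 0L else st, output = out)
  }

  # masscalc prints the formula and adduct table
  mc <- run_cli("masscalc", "--annotation", shQuote("PC 16:0/18:1"))
  expect_identical(mc$status, 0L)
  expect_true(any(grepl("C42H82NO8P", mc$output)))

  dir <- withr::local_tempdir()
  sim_out <- run_cli("simulate", "--preset", "lpc_18_1_mix",
                     "--seed", "5", "--out", file.path(dir, "sim"))
  expect_identical(sim_out$status, 0L)
  expect_true(file.exists(file.path(dir, "sim", "run.tsv")))

  ann_file <- file.path(dir, "annotations.tsv")
  readr::write_tsv(tibble::tibble(annotation = "LPC 18:1",
                                  retention_time_min = 10), ann_file)
  tg <- run_cli("targets", "--annotations", ann_file,
                "--out", file.path(dir, "targets.tsv"))
  expect_identical(tg$status, 0L)
  targets <- readr::read_tsv(file.path(dir, "targets.tsv"),
                             show_col_types = FALSE)
  expect_identical(nrow(targets), 1L)

  an <- run_cli("annotate", "--run", file.path(dir, "sim", "run.tsv"),
                "--annotations", ann_file,
                "--out", file.path(dir, "report"))
  expect_identical(an$status, 0L)
  quant <- readr::read_tsv(file.path(dir, "report",
                                     "isomer_quantities.tsv"),
                           show_col_types = FALSE)
  # CLI result equals the in-process pipeline on the same inputs
  sim <- simulate_run(preset_scenarios("lpc_18_1_mix", seed = 5))
  res <- annotate_run(sim$run, parse_annotations(tibble::tibble(
    annotation = "LPC 18:1", retention_time_min = 10)))
  expect_equal(sort(quant$relative_abundance),
               sort(res$abundances$relative_abundance), tolerance = 1e-9)

  # user errors exit 1
  bad <- run_cli("targets", "--annotations", "missing.tsv",
                 "--out", file.path(dir, "x.tsv"))
  expect_identical(bad$status, 1L)
  unk <- run_cli("frobnicate")
  expect_identical(unk$status, 1L)
})
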