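# Run I/O, peak matching, chromatogram extraction, RT validation.

tiny_run <- function() {
  scans <- tibble::tibble(
    scan_id = 1:4, ms_level = c(1L, 1L, 1L, 2L),
    rt = c(9.9, 10.0, 10.1, 10.05), polarity = "+",
    precursor_mz = c(NA, NA, NA, 500.25),
    isolation_width = c(NA, NA, NA, 1)
  )
  peaks <- tibble::tibble(
    scan_id = c(1L, 2L, 2L, 3L, 4L),
    mz = c(522.3555, 522.3555, 600.1, 522.3555, 184.0733),
    intensity = c(50, 100, 10, 50, 30)
  )
  ms_run(scans, peaks)
}

test_that("the TSV peak-list dialect round-trips a run", {
  run <- tiny_run()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_run(run, f)
  back <- read_run(f)
  expect_identical(nrow(back$scans), nrow(run$scans))
  expect_equal(sort(back$peaks$mz), sort(run$peaks$mz), tolerance = 1e-9)
  expect_equal(sort(back$peaks$intensity), sort(run$peaks$intensity))
  expect_identical(sum(back$scans$ms_level == 2), 1L)
  expect_equal(back$scans$precursor_mz[back$scans$ms_level == 2], 500.25)
})

test_that("mzML round-trips through the mzR reader/writer", {
  run <- simulate_run(preset_scenarios("pe_pair"))$run
  f <- withr::local_tempfile(fileext = ".mzML")
  write_run(run, f)
  back <- read_run(f)
  expect_identical(nrow(back$scans), nrow(run$scans))
  expect_identical(nrow(back$peaks), nrow(run$peaks))
  expect_lt(max(abs(back$peaks$mz - run$peaks$mz)), 1e-6)
  expect_equal(back$peaks$intensity, run$peaks$intensity,
               tolerance = 1e-6)
  expect_equal(back$scans$rt, run$scans$rt, tolerance = 1e-6)
})

test_that("reading a missing or truncated file errors", {
  expect_error(read_run("does-not-exist.tsv"), "no such file")
  f <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<mzML>this is not valid</mz", f)
  expect_error(suppressWarnings(read_run(f)))
})

test_that("match_peak applies an inclusive ppm window with an intensity tie-break", {
  peaks <- tibble::tibble(mz = c(172.1108), intensity = c(100))
  # 5.2 ppm away: outside a 5 ppm window
  expect_null(match_peak(peaks, 172.1099, 5))
  expect_identical(match_peak(peaks, 172.1099, 6)$mz, 172.1108)
  # exact match
  exact <- tibble::tibble(mz = 172.1099, intensity = 7)
  expect_identical(match_peak(exact, 172.1099, 5)$intensity, 7)
  # two in-tolerance peaks: the more intense one wins
  two <- tibble::tibble(mz = c(172.1100, 172.1098), intensity = c(5, 50))
  expect_identical(match_peak(two, 172.1099, 5)$mz, 172.1098)
  # near-symmetry of the ppm error under target/observed swap
  ppm <- function(a, b) abs(a - b) / b * 1e6
  expect_lt(abs(ppm(172.1108, 172.1099) - ppm(172.1099, 172.1108)), 0.01)
})

test_that("EIC extraction finds the apex and integrates the area", {
  sim <- simulate_run(preset_scenarios("pc_22_6"))
  prec_mz <- adduct_mz(composition("PC 16:0/22:6"), "[M+H]+")
  eic <- extract_eic(sim$run, prec_mz, tol_ppm = 5)
  expect_equal(attr(eic, "apex_rt"), 12.0,
               tolerance = sim$spec$scan_interval + 1e-9)
  expect_gt(attr(eic, "area"), 0)
  # absent target: all-zero EIC with zero area
  empty <- extract_eic(sim$run, 1234.5678, tol_ppm = 5)
  expect_true(all(empty$intensity == 0))
  expect_identical(attr(empty, "area"), 0)
  # area is invariant under scan-order shuffling (extract sorts by RT)
  shuffled <- sim$run
  set.seed(7)
  ord <- sample(nrow(shuffled$scans))
  shuffled <- ms_run(shuffled$scans[ord, ], shuffled$peaks)
  eic2 <- extract_eic(shuffled, prec_mz, tol_ppm = 5)
  expect_equal(attr(eic2, "area"), attr(eic, "area"), tolerance = 1e-9)
  # two nearby targets within one wide window sum together
  scans <- tibble::tibble(scan_id = 1:2, ms_level = 1L, rt = c(1, 2),
                          polarity = "+", precursor_mz = NA_real_,
                          isolation_width = NA_real_)
  peaks <- tibble::tibble(scan_id = c(1L, 1L),
                          mz = c(500.0000, 500.0010),
                          intensity = c(10, 20))
  both <- extract_eic(ms_run(scans, peaks), 500.0005, tol_ppm = 10)
  expect_equal(both$intensity[1], 30)
})

test_that("retention-time validation passes at the true apex and fails off it", {
  sim <- simulate_run(preset_scenarios("pc_22_6"))
  ann <- "PC 16:0/22:6(n-3,6,9,12,15,18)"
  ok <- validate_rt(sim$run, ann, expected_rt = 12.0, window = 0.2)
  expect_true(ok$pass)
  shifted <- validate_rt(sim$run, ann, expected_rt = 12.5, window = 0.2)
  expect_false(shifted$pass)
  # absent precursor: fail with zero apex intensity
  absent <- validate_rt(sim$run, "PC 18:0/18:1(n-9)", expected_rt = 12,
                        window = 0.2)
  expect_false(absent$pass)
  expect_identical(absent$apex_intensity, 0)
})

test_that("PRM scans are assigned to the nearest in-window target", {
  run <- tiny_run()
  targets <- tibble::tibble(
    mz = c(500.31, 500.22), polarity = "+",
    rt_start_min = 10, rt_end_min = 10.1,
    nce = 15, annotation = c("far", "near")
  )
  got <- assign_prm_scans(run, targets)
  expect_identical(nrow(got), 1L)
  expect_identical(got$annotation, "near")
  # outside the RT window: unassigned
  targets$rt_start_min <- 11; targets$rt_end_min <- 12
  expect_identical(nrow(assign_prm_scans(run, targets)), 0L)
})
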