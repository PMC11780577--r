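# Theoretical product generation: cleavages, MS1 ozonolysis products,
# derivatized precursors, class-specific MS2 diagnostic ions, PRM targets.

test_that("cleavage enumeration assigns u as the count of lower positions", {
  cl <- enumerate_cleavages("FA 22:4(n-6,9,12,15)")
  expect_identical(cl$p, c(6L, 9L, 12L, 15L))
  expect_identical(cl$u, 0:3)
  expect_false(any(cl$mass_degenerate))

  one <- enumerate_cleavages("FA 18:1(n-9)")
  expect_identical(nrow(one), 1L)
  expect_identical(one$p, 9L)

  deg <- enumerate_cleavages("PE 16:1(n-7)_18:1(n-7)")
  expect_identical(nrow(deg), 2L)
  expect_true(all(deg$mass_degenerate))

  expect_error(enumerate_cleavages("PC 18:1_18:1"), "unresolved")
})

test_that("MS1 ozonolysis products have the right masses and counts", {
  oz <- ozesi_products("FA 18:1(n-9)", "-")
  ald <- oz[oz$role == "ozesi_aldehyde", ]
  expect_identical(ald$formula, "C9H16O3")  # 9-oxononanoic acid
  expect_equal(ald$mz, 171.1027, tolerance = 1e-4)
  cri <- oz[oz$role == "ozesi_criegee", ]
  expect_equal(cri$mz - ald$mz, 15.9949, tolerance = 1e-4)

  four <- ozesi_products("PC 17:0/22:4(n-6,9,12,15)")
  expect_identical(sum(four$role == "ozesi_aldehyde"), 4L)

  expect_identical(nrow(ozesi_products("PC 16:0/18:0")), 0L)
})

test_that("all C=C converge to a single derivatized precursor m/z", {
  prec <- oznox_precursor("PC 17:0/22:4(n-6,9,12,15)")
  expect_identical(nrow(prec), 1L)
  # ensemble mass ignores the position pattern
  alt <- oznox_precursor("PC 17:0/22:4(n-7,10,13,16)")
  expect_identical(prec$mz, alt$mz)
  # PC precursor: M + NO4 - H (no ammonium)
  expect_equal(prec$mz,
               adduct_mz(composition("PC 17:0/22:4"), "[M+NO4-H]+"))
  # ammonium-adduct classes gain NH3 by default, configurable off
  fa <- composition("FA 18:1")
  expect_equal(oznox_precursor("FA 18:1(n-9)")$mz,
               adduct_mz(fa, "[M+NO4-H+NH3]+"))
  expect_equal(oznox_precursor("FA 18:1(n-9)", ammoniate = FALSE)$mz,
               adduct_mz(fa, "[M+NO4-H]+"))
  expect_equal(oznox_precursor("FA 18:1(n-9)", ammoniate = FALSE)$mz,
               359.2303, tolerance = 1e-4)
  # negative mode: both registered variants work, default [M+N2O7]-
  neg <- oznox_precursor("FA 18:1(n-9)", "-")
  expect_equal(neg$mz, adduct_mz(fa, "[M+N2O7]-"))
  negH <- oznox_precursor("FA 18:1(n-9)", "-",
                          negative_adduct = "[M+N2O7-H]-")
  # both carry one negative charge, so they differ by a neutral hydrogen
  expect_equal(neg$mz - negH$mz, 1.0078250, tolerance = 1e-6)
  expect_error(oznox_precursor("PC 16:0/18:0"), "saturated")
})

test_that("diagnostic-ion multiplicity per C=C follows the class rules", {
  counts <- c("PC 16:0/18:1(n-9)" = 2L, "LPC 18:1(n-9)" = 2L,
              "LPE 18:1(n-9)" = 3L, "FA 18:1(n-9)" = 3L,
              "PE 16:0/18:1(n-9)" = 4L, "PG 16:0/18:1(n-9)" = 2L,
              "PI 16:0/18:1(n-9)" = 2L, "PS 16:0/18:1(n-9)" = 2L,
              "PA 16:0/18:1(n-9)" = 2L, "LPG 18:1(n-9)" = 2L)
  for (ann in names(counts)) {
    expect_identical(nrow(oznox_ms2_products(ann)), counts[[ann]],
                     label = ann)
  }
  # six pairs for the hexaunsaturated docosahexaenoyl chain
  pc226 <- oznox_ms2_products("PC 16:0/22:6(n-3,6,9,12,15,18)")
  expect_identical(nrow(pc226), 12L)
})

test_that("PC MS2 aldehydes equal the MS1 ozonolysis aldehyde m/z", {
  ms2 <- oznox_ms2_products("PC 16:0/22:6(n-3,6,9,12,15,18)")
  ms1 <- ozesi_products("PC 16:0/22:6(n-3,6,9,12,15,18)")
  a2 <- sort(ms2$mz[ms2$role == "ms2_aldehyde"])
  a1 <- sort(ms1$mz[ms1$role == "ozesi_aldehyde"])
  expect_equal(a2, a1, tolerance = 1e-9)
  # companion ion sits exactly one CHO below
  pair <- ms2[ms2$p == 9, ]
  expect_equal(pair$mz[pair$role == "ms2_aldehyde"] -
                 pair$mz[pair$role == "ms2_aldehyde_minus_CHO"],
               29.0027, tolerance = 1e-4)
})

test_that("headgroup-lost product ions converge across PE/PG/PI/PS/PA", {
  classes <- c("PE", "PG", "PI", "PS", "PA")
  sets <- lapply(classes, function(cl) {
    prod <- oznox_ms2_products(paste0(cl, " 16:0/18:2(n-6,9)"))
    sort(prod$mz[grepl("headgroup_lost", prod$role)])
  })
  for (i in 2:length(sets)) {
    expect_lt(max(abs(sets[[1]] - sets[[i]])), 1e-6)
  }
  # the headgroup neutral losses themselves
  nl <- function(cl) {
    r <- class_rules()
    monoisotopic_mass(parse_formula(r$headgroup_loss[r$lipid_class == cl]))
  }
  expect_equal(nl("PE"), 141.0191, tolerance = 1e-4)
  expect_equal(nl("PG"), 172.0137, tolerance = 1e-4)
  expect_equal(nl("PS"), 185.0089, tolerance = 1e-4)
  expect_equal(nl("PI"), 260.0297, tolerance = 1e-4)
  expect_equal(nl("PA"), 97.9769, tolerance = 1e-4)
})

test_that("coeluting-aldehyde collision: n-15 of 22:4 equals n-11 of 18:1", {
  a_224 <- aldehyde_formula("LPC 22:4(n-6,9,12,15)", 15, 3)
  a_181 <- aldehyde_formula("LPC 18:1(n-11)", 11, 0)
  expect_identical(a_224, a_181)
})

test_that("aldehyde m/z decreases with p (fixed u) and increases with u (fixed p)", {
  ann <- "PC 16:0/22:6(n-3,6,9,12,15,18)"
  m <- function(p, u) monoisotopic_mass(aldehyde_formula(ann, p, u))
  expect_true(all(diff(sapply(c(3, 6, 9, 12), m, u = 0)) < 0))
  expect_true(all(diff(sapply(0:3, function(u) m(12, u))) > 0))
})

test_that("PRM targets carry class collision energies and RT windows", {
  anns <- parse_annotations(tibble::tibble(
    annotation = c("PE 16:0/18:1(n-9)", "PC 16:0/18:1(n-9)",
                   "FA 18:1(n-9)", "PC 16:0/18:0"),
    retention_time_min = c(14, 15, 3, 16)
  ))
  tg <- build_prm_targets(anns, rt_window_min = 0.5)
  expect_identical(nrow(tg), 3L)  # saturated species dropped
  expect_equal(tg$nce[tg$annotation == "FA 18:1(n-9)"], 10)
  expect_equal(tg$nce[tg$annotation == "PE 16:0/18:1(n-9)"], 25)
  expect_equal(tg$nce[tg$annotation == "PC 16:0/18:1(n-9)"], 15)
  expect_true(all(tg$rt_end_min - tg$rt_start_min == 1))
  expect_true(!is.unsorted(tg$rt_start_min))
  # missing retention time is an error
  no_rt <- parse_annotations("FA 18:1(n-9)")
  expect_error(build_prm_targets(no_rt), "retention time")
  # all-saturated input gives an empty table, not an error
  sat <- parse_annotations(tibble::tibble(annotation = "PC 16:0/18:0",
                                          retention_time_min = 16))
  expect_identical(nrow(build_prm_targets(sat)), 0L)
})
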