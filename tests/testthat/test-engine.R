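# Diagnostic-ion detection, candidate enumeration, scoring, replicate
# alignment.

test_that("detection recovers every seeded cleavage event", {
  sim <- simulate_run(preset_scenarios("pc_22_6"))
  det <- detect_events(sim$run, "PC 16:0/22:6")
  expect_identical(det$p, c(3L, 6L, 9L, 12L, 15L, 18L))
  expect_identical(det$u, 0:5)
  expect_true(all(det$n_scans >= 3))

  sim_fa <- simulate_run(preset_scenarios("fa_16_1_seven_isomers"))
  det_fa <- detect_events(sim_fa$run, "FA 16:1")
  expect_identical(sort(det_fa$p), sort(c(5L, 6L, 7L, 9L, 10L, 11L, 12L)))
  expect_true(all(det_fa$u == 0L))

  # saturated species produce nothing
  expect_identical(nrow(detect_events(sim$run, "PC 16:0/18:0")), 0L)
})

test_that("detection requires co-occurring roles across enough scans", {
  sim <- simulate_run(preset_scenarios("lpc_18_1_mix"))
  # with an absurd min_scans nothing qualifies
  none <- detect_events(sim$run, "LPC 18:1", min_scans = 1000)
  expect_identical(nrow(none), 0L)
  # a run without PRM scans errors
  ms1_only <- ms_run(sim$run$scans[sim$run$scans$ms_level == 1, ],
                     sim$run$peaks)
  expect_error(detect_events(ms1_only, "LPC 18:1"), "no PRM scans")
})

test_that("candidate chaining reproduces the diunsaturated example set", {
  det <- tibble::tibble(p = c(6L, 9L, 9L, 12L), u = c(0L, 1L, 0L, 1L)) |>
    dplyr::distinct()
  cand <- enumerate_candidates("FA 18:2", det)
  expect_setequal(cand$candidate,
                  c("FA 18:2(n-6,9)", "FA 18:2(n-9,12)", "FA 18:2(n-6,12)"))
  # single event, monounsaturated: one candidate
  single <- enumerate_candidates("FA 18:1",
                                 tibble::tibble(p = 7L, u = 0L))
  expect_identical(single$candidate, "FA 18:1(n-7)")
  # an inconsistent detected set gives zero candidates, no error
  bad <- enumerate_candidates("FA 18:1", tibble::tibble(p = 9L, u = 1L))
  expect_identical(nrow(bad), 0L)
})

test_that("enumeration equals the brute-force oracle on random detected sets", {
  set.seed(2024)
  for (i in 1:60) {
    c_ <- sample(8:22, 1)
    d_ <- sample(1:3, 1)
    ann <- sprintf("FA %d:%d", c_, d_)
    le <- legal_events(ann)
    det <- le[sample(nrow(le), min(nrow(le), sample(2:6, 1))), ]
    got <- package_signatures(ann, det)
    want <- oracle_candidates(list(list(c = c_, d = d_)), det)
    expect_identical(got, want, label = paste(ann, "case", i))
  }
  # two-chain species against the oracle
  det2 <- tibble::tibble(p = c(7L, 9L, 11L), u = 0L)
  got2 <- package_signatures("PE 16:1_18:1", det2)
  want2 <- oracle_candidates(list(list(c = 16, d = 1), list(c = 18, d = 1)),
                             det2)
  expect_identical(got2, want2)
})

test_that("mass-degenerate two-chain assignments merge into one candidate", {
  det <- tibble::tibble(p = 7L, u = 0L)
  cand <- enumerate_candidates("PE 16:1_18:1", det)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$candidate, "PE 16:1(n-7)_18:1(n-7)")
  expect_true(cand$expected[[1]]$degenerate)
  # swapped equal patterns across chains merge with ambiguity marked
  det2 <- tibble::tibble(p = c(7L, 9L), u = 0L)
  cand2 <- enumerate_candidates("PE 16:1_18:1", det2)
  sw <- cand2[cand2$signature == "7/0;9/0", ]
  expect_identical(nrow(sw), 1L)
  expect_true(sw$ambiguous_chains)
})

test_that("sum compositions enumerate positions on a pseudo-chain", {
  det <- tibble::tibble(p = c(6L, 9L, 12L), u = 0:2)
  cand <- enumerate_candidates("PC 37:3", det)
  expect_identical(cand$candidate, "PC 37:3(n-6,9,12)")
})

test_that("scores combine coverage and purity and normalize to probabilities", {
  # one candidate explaining everything scores 1
  det1 <- fake_detected(tibble::tibble(p = 9, u = 0, intensity = 100))
  c1 <- fake_candidates(list(tibble::tibble(p = 9, u = 0)))
  s1 <- score_candidates(c1, det1)
  expect_equal(s1$score, 1)
  expect_equal(s1$probability, 1)

  # two monounsaturated candidates at 90/10 intensity: purity terms
  det2 <- fake_detected(tibble::tibble(p = c(9, 7), u = 0,
                                       intensity = c(900, 100)))
  c2 <- fake_candidates(list(tibble::tibble(p = 9, u = 0),
                             tibble::tibble(p = 7, u = 0)))
  s2 <- score_candidates(c2, det2)
  expect_equal(s2$score[s2$candidate == "cand1"], 0.9)
  expect_equal(s2$score[s2$candidate == "cand2"], 0.1)
  expect_equal(sum(s2$probability), 1)

  # candidate missing one of four expected events: coverage 3/4
  det3 <- fake_detected(tibble::tibble(p = c(6, 9, 12), u = 0:2,
                                       intensity = 100))
  c3 <- fake_candidates(list(tibble::tibble(p = c(6, 9, 12, 15), u = 0:3)))
  s3 <- score_candidates(c3, det3)
  expect_equal(s3$score, 0.75)

  # scores are invariant under uniform intensity scaling
  det2b <- fake_detected(tibble::tibble(p = c(9, 7), u = 0,
                                        intensity = c(900, 100) * 1e4))
  s2b <- score_candidates(c2, det2b)
  expect_equal(s2b$score, s2$score)

  # the probability floor drops trace candidates and renormalizes
  det4 <- fake_detected(tibble::tibble(p = c(9, 7), u = 0,
                                       intensity = c(999, 1)))
  s4 <- score_candidates(c2, det4, probability_floor = 0.01)
  expect_identical(nrow(s4), 1L)
  expect_equal(s4$probability, 1)
})

test_that("unique-event bookkeeping marks events owned by one candidate", {
  c2 <- fake_candidates(list(tibble::tibble(p = c(6, 9), u = 0:1),
                             tibble::tibble(p = c(6, 12), u = 0:1)))
  det <- fake_detected(tibble::tibble(p = c(6, 9, 12), u = c(0, 1, 1),
                                      intensity = 100))
  s <- score_candidates(c2, det, probability_floor = 0)
  expect_identical(s$n_unique_events, c(1L, 1L))  # (9,1) and (12,1)
})

test_that("replicate alignment averages scores by run intensity", {
  det <- fake_detected(tibble::tibble(p = c(9, 7), u = 0,
                                      intensity = c(900, 100)))
  cands <- fake_candidates(list(tibble::tibble(p = 9, u = 0),
                                tibble::tibble(p = 7, u = 0)))
  s <- score_candidates(cands, det, probability_floor = 0)
  # identical replicates leave scores unchanged
  m <- align_replicates(list(s, s))
  expect_equal(sort(m$score), sort(s$score))
  # one empty replicate halves the scores under equal weights
  m2 <- align_replicates(list(s, s[0, ]))
  expect_equal(sort(m2$score), sort(s$score) / 2)
  # three replicates with intensity-proportional weights: weighted mean
  s_b <- s; s_b$score <- c(0.5, 0.5)
  m3 <- align_replicates(list(s, s, s_b), run_intensity = c(1, 1, 2))
  for (sig in s$signature) {
    want <- (s$score[s$signature == sig] * 0.25 * 2 +
               s_b$score[s_b$signature == sig] * 0.5)
    expect_equal(m3$score[m3$signature == sig], want)
  }
  expect_equal(sum(m3$probability), 1)
})

test_that("a noiseless single-truth run yields probability ~1 for the truth", {
  for (preset in c("pc_22_6", "pe_pair")) {
    sim <- simulate_run(preset_scenarios(preset))
    ann <- sub("\\(.*", "", sim$truth$annotation[1])
    ann <- gsub("\\(n-[0-9,]+\\)", "", sim$truth$annotation[1])
    det <- detect_events(sim$run, ann)
    cand <- enumerate_candidates(ann, det)
    s <- score_candidates(cand, det)
    top <- s[which.max(s$probability), ]
    expect_identical(top$candidate, sim$truth$annotation[1])
    expect_gte(top$probability, 0.99)
  }
})
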