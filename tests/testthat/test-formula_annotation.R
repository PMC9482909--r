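# Formula enumeration, isotope scoring, MS/MS consistency, candidate ranking.

test_that("formula enumeration equals the nested-loop oracle", {
  for (mass in c(117.078979,            # valine
                 122.048013,            # nicotinamide neutral
                 166.062994,            # 3-HPPA neutral
                 131.094629)) {         # alanine betaine neutral
    got <- enumerate_formulas(mass, tol_ppm = 5,
                              element_bounds = c(C = 15, H = 30, N = 3, O = 5))
    want <- oracle_enumerate_chno(mass, 5, 15, 30, 3, 5)
    expect_setequal(got$formula, want)
  }
  expect_true("C5H11NO2" %in%
                enumerate_formulas(117.078979, 5,
                                   element_bounds = c(C = 15, H = 30, N = 3, O = 5))$formula)
})

test_that("enumeration handles bare carbon and is monotone in tolerance", {
  expect_equal(enumerate_formulas(12.000, 5,
                                  element_bounds = c(C = 3, H = 6, N = 1, O = 1))$formula,
               "C")
  wide <- enumerate_formulas(117.078979, 5)
  narrow <- enumerate_formulas(117.078979, 0.1)
  expect_true(all(narrow$formula %in% wide$formula))
  expect_error(enumerate_formulas(500, 5, max_combinations = 50), "tighten")
})

test_that("isotope score follows its definition and clips to [0, 1]", {
  pat <- isotope_pattern("C10H20O5", max_peaks = 3)
  expect_equal(iso_score(pat, pat), 1)
  obs <- data.frame(mass = c(100, 101), abundance = c(1, 0))
  theo <- data.frame(mass = c(100, 101), abundance = c(1, 0.30))
  expect_equal(iso_score(obs, theo), 0.85)
  way_off <- data.frame(mass = c(100, 101, 102), abundance = c(1, 1, 1))
  theo2 <- data.frame(mass = c(100, 101, 102), abundance = c(1, 0, 0))
  expect_gte(iso_score(way_off, theo2), 0)
})

test_that("MS/MS consistency scores the explainable intensity fraction", {
  cand <- "C8H10N4O2"
  # explainable peaks: protonated candidate and candidate minus CO / CH3N
  mzs <- c(adduct_mz(cand, "[M+H]+"),
           monoisotopic_mass("C7H10N4O") + 1.00727646,
           monoisotopic_mass("C7H7N3O2") + 1.00727646)
  full <- new_spectrum(mzs, c(1, 1, 1))
  expect_equal(ann_sim(full, cand)$ann_sim_form, 1)
  none <- new_spectrum(c(77.5111, 91.5222, 120.5333), c(1, 1, 1))
  expect_equal(ann_sim(none, cand)$ann_sim_form, 0)
  two_of_three <- new_spectrum(c(mzs[1:2], 120.5333), c(1, 1, 1))
  as <- ann_sim(two_of_three, cand)
  expect_equal(as$ann_sim_form, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(as$ann_sim_form, 0.816, tolerance = 1e-3)
  # library structure evidence caps the compound-level score
  expect_equal(ann_sim(two_of_three, cand, library_dot = 30)$ann_sim_comp, 0.30)
  expect_equal(as$ann_sim_comp, as$ann_sim_form)
})

test_that("candidate ranking is total, deterministic and exposes gaps", {
  single <- rank_candidates(data.frame(formula = "C2H6O", ppm_error = 0.5))
  expect_equal(single$rank, 1L)
  expect_equal(single$gap_iso, Inf)

  two <- rank_candidates(data.frame(formula = c("C6H12O6", "C7H16O5"),
                                    ppm_error = c(1, 0.2),
                                    iso_score = c(0.95, 0.60)))
  expect_equal(two$formula[1], "C6H12O6")   # iso score dominates ppm
  expect_equal(two$gap_iso[1], 0.35)
  expect_gt(two$gap_iso[1], 0.2)

  tied <- rank_candidates(data.frame(formula = c("C7H16O5", "C6H12O6"),
                                     ppm_error = c(1, 1),
                                     iso_score = c(0.8, 0.8)))
  expect_equal(tied$formula, c("C6H12O6", "C7H16O5"))  # Hill-string order
  expect_equal(tied$gap_iso[1], 0)

  # permuting input order never changes the ranking
  set.seed(601)
  cand <- data.frame(formula = sprintf("C%dH%d", 5:10, 10:15),
                     ppm_error = runif(6, -3, 3), iso_score = runif(6),
                     ann_sim_form = runif(6))
  r1 <- rank_candidates(cand)
  for (i in 1:5) {
    r2 <- rank_candidates(cand[sample(6), ])
    expect_equal(r2$formula, r1$formula)
    expect_equal(r2$gap_iso, r1$gap_iso)
  }
})
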