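# Formula parsing, monoisotopic/adduct masses, ppm errors, isotope patterns.

test_that("formula parsing reproduces element multisets and round-trips", {
  expect_equal(parse_formula("C5H11NO2"),
               c(C = 5L, H = 11L, N = 1L, O = 2L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C6H6N2O"), c(C = 6L, H = 6L, N = 2L, O = 1L))
  # repeated symbols accumulate; Hill serialization is canonical
  expect_equal(formula_string(parse_formula("CH3CH2OH")), "C2H6O")
  for (f in c("C5H11NO2", "H2O", "C24H40O5", "C6H8O7", "CHNO", "C2H6NaO4P"))
    expect_identical(formula_string(parse_formula(f)), formula_string(f))
  expect_error(parse_formula("C5Xx2"), "Xx")
  expect_error(parse_formula("C0H4"), "zero")
  expect_error(parse_formula(""), "non-empty")
})

test_that("monoisotopic masses match independent hand sums", {
  expect_equal(monoisotopic_mass("C5H11NO2"), 117.078979, tolerance = 1e-8)
  expect_equal(monoisotopic_mass("H2"), 2 * 1.0078250319, tolerance = 1e-12)
  expect_equal(monoisotopic_mass("C"), 12, tolerance = 1e-12)
})

test_that("adduct m/z reproduces the printed measured values within 5 ppm", {
  printed <- list(
    list("C5H11NO2",  "[M+H]+", 118.0861),  # valine
    list("C5H14NO",   "[M]+",   104.1067),  # choline (quaternary cation)
    list("C6H13NO2",  "[M+H]+", 132.1016),  # alanine betaine
    list("C6H6N2O",   "[M+H]+", 123.0550),  # nicotinamide
    list("C6H5NO2",   "[M+H]+", 124.0389),  # isonicotinic acid
    list("C9H11NO4",  "[M+H]+", 198.0756),  # levodopa
    list("C24H40O5",  "[M-H]-", 407.2804),  # cholic acid
    list("C26H43NO6", "[M-H]-", 464.3015)   # glycocholic acid
  )
  for (p in printed)
    expect_lt(abs(ppm_error(p[[3]], adduct_mz(p[[1]], p[[2]]))), 5)
  # exact theoretical values
  expect_equal(adduct_mz("C5H11NO2", "[M+H]+"), 118.086255, tolerance = 1e-6)
  expect_equal(adduct_mz("C5H14NO", "[M]+"), 104.106990, tolerance = 1e-6)
  expect_equal(adduct_mz("C24H40O5", "[M-H]-"), 407.280298, tolerance = 1e-6)
})

test_that("protonated and deprotonated species differ by two proton masses", {
  for (f in c("C5H11NO2", "C6H6N2O", "C24H40O5", "C10H12N2O"))
    expect_equal(adduct_mz(f, "[M+H]+") - adduct_mz(f, "[M-H]-"),
                 2 * 1.00727646, tolerance = 1e-7)
})

test_that("adduct names tolerate whitespace and unicode minus on input", {
  expect_identical(parse_adduct("[M + H] +")$name, "[M+H]+")
  expect_identical(parse_adduct("[M−H]-")$name, "[M-H]-")
  expect_error(parse_adduct("[M+2H]2+"), "unsupported")
})

test_that("ppm error follows its definition", {
  expect_equal(ppm_error(118.0861, 118.086255), -1.31, tolerance = 0.01)
  expect_equal(ppm_error(321.1234, 321.1234), 0)
  expect_equal(ppm_error(100.0010, 100.0000), 10, tolerance = 1e-9)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("isotope patterns match closed-form single-element expectations", {
  c1 <- isotope_pattern("C", max_peaks = 2)
  expect_equal(c1$abundance[2] / c1$abundance[1], 0.0107 / 0.9893,
               tolerance = 1e-9)
  h2o <- isotope_pattern("H2O", max_peaks = 3)
  expect_equal(h2o$abundance[2],
               2 * 0.000115 / 0.999885 + 0.00038 / 0.99757, tolerance = 1e-6)
  # binomial closed form for a pure-carbon cluster (A+1 is the base peak)
  c100 <- isotope_pattern("C100", max_peaks = 3)
  expect_equal(c100$abundance[2] / c100$abundance[1], 100 * 0.0107 / 0.9893,
               tolerance = 1e-9)
})

test_that("isotope pattern envelope is a probability distribution", {
  for (f in c("C5H11NO2", "C24H40O5", "C6H8O7", "C2H6NaO4P", "CCl3F")) {
    pat <- isotope_pattern(f, max_peaks = 4)
    expect_equal(sum(attr(pat, "raw_abundance")), 1, tolerance = 1e-9)
    expect_true(all(diff(pat$mass) > 0))
    expect_equal(max(pat$abundance), 1)
    # truncation only drops trailing peaks
    pat2 <- isotope_pattern(f, max_peaks = 2)
    expect_equal(pat2$mass, pat$mass[1:2])
  }
  expect_error(isotope_pattern("C6H6", max_peaks = 1), "max_peaks")
})
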