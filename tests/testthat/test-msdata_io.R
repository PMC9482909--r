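# MSP, feature-table and suspect-list readers/writers.

test_that("MSP records round-trip through write and read", {
  specs <- list(
    new_spectrum(c(81.0699, 110.0600, 123.0553), c(100, 45, 80),
                 precursor_mz = 123.0553, precursor_type = "[M+H]+",
                 name = "nicotinamide-like", formula = "C6H6N2O",
                 inchikey = "AAAAAAAAAAAAAA-BBBBBBBBSA-N",
                 metadata = list(COMMENT = "synthetic fixture")),
    new_spectrum(c(59.0128, 89.0233), c(10, 100), name = "anon")
  )
  p <- withr::local_tempfile(fileext = ".msp")
  write_msp(specs, p)
  back <- read_msp(p)
  expect_length(back, 2L)
  expect_equal(back[[1]]$mz, specs[[1]]$mz, tolerance = 1e-4)
  expect_equal(back[[1]]$intensity, specs[[1]]$intensity, tolerance = 1e-4)
  expect_identical(back[[1]]$name, "nicotinamide-like")
  expect_identical(back[[1]]$metadata$COMMENT, "synthetic fixture")
  expect_true(back[[1]]$structure_known)
  # record lacking an InChIKey has unknown structure
  expect_false(back[[2]]$structure_known)
})

test_that("MSP parser enforces the declared peak count and dialect variants", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("NAME: broken", "Num Peaks: 3", "100.0 1", "200.0 2", ""), p)
  expect_error(read_msp(p), "peak-count mismatch")
  writeLines(c("NAME: ok", "NumPeaks: 2", "100.0\t1", "200.0 2", ""), p)
  expect_length(read_msp(p), 1L)
  writeLines(character(0), p)
  expect_warning(out <- read_msp(p), "empty")
  expect_length(out, 0L)
})

test_that("feature tables read against a design with strict validation", {
  des <- cohort_design(c("S1", "S2", "Q1", "Q2"),
                       c("PD", "Ctrl", "QC", "QC"))
  tab <- data.frame(feature_id = sprintf("F%d", 1:5), mz = 100:104 + 0.5,
                    rt = 1:5, esi_mode = "+", lc_mode = "RP",
                    fraction = "polar",
                    S1 = 1:5, S2 = 6:10, Q1 = 11:15, Q2 = 16:20)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  fs <- read_feature_table(p, des)
  expect_equal(dim(fs$intensities), c(5L, 4L))
  expect_equal(unname(fs$intensities["F3", "S2"]), 8)

  write.csv(cbind(tab, ORPHAN = 1), p, row.names = FALSE)
  expect_error(read_feature_table(p, des), "ORPHAN")

  tab2 <- tab; tab2$feature_id[2] <- "F1"
  write.csv(tab2, p, row.names = FALSE)
  expect_error(read_feature_table(p, des), "duplicated feature_id")

  tab3 <- tab; tab3$S1 <- as.character(tab3$S1); tab3$S1[4] <- "oops"
  write.csv(tab3, p, row.names = FALSE)
  expect_error(read_feature_table(p, des), "row 4.*'S1'")
})

test_that("samples missing from the table are zero-filled with a warning", {
  des <- cohort_design(c("S1", "S2", "S3"), c("PD", "Ctrl", "QC"))
  mat <- matrix(1:4, 2, 2, dimnames = list(c("F1", "F2"), c("S1", "S2")))
  expect_warning(fs <- make_toy_fs(mat, des), "S3")
  expect_equal(unname(fs$intensities[, "S3"]), c(0, 0))
})

test_that("suspect lists backfill mass from formula and skip bare rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(name = c("L-Valine", "nameless", "masses-only"),
                       formula = c("C5H11NO2", "", ""),
                       monoisotopic_mass = c(NA, NA, 200.1),
                       inchikey = c("K1", "", "K3")),
            p, row.names = FALSE)
  expect_warning(sus <- read_suspect_list(p, "LITMIN"), "skipped")
  expect_equal(nrow(sus), 2L)
  expect_equal(sus$neutral_mass[1], 117.078979, tolerance = 1e-6)
  expect_identical(unique(sus$list_code), "LITMIN")

  # a 59-row list yields 59 entries
  big <- data.frame(name = sprintf("cmp%02d", 1:59),
                    formula = sprintf("C%dH%d", 5:63, 2 * (5:63)))
  write.csv(big, p, row.names = FALSE)
  expect_equal(nrow(read_suspect_list(p, "D020920")), 59L)

  # declared mass must agree with the formula
  write.csv(data.frame(name = "bad", formula = "C5H11NO2",
                       monoisotopic_mass = 117.20), p, row.names = FALSE)
  expect_error(read_suspect_list(p, "X"), "disagrees")
})

test_that("cohort design rejects malformed input", {
  expect_error(cohort_design(c("a", "a"), c("PD", "QC")), "duplicated")
  expect_error(cohort_design("a", "Case"), "group labels")
})
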