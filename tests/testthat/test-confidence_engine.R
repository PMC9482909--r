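# The identification-confidence rule matrix: one case per rule cell across
# the three schemes, plus cascade totality and monotonicity.

test_that("the suspect-screening cascade assigns each rule cell its level", {
  cases <- list(
    # library score > 0.9 with a single candidate
    list(make_evidence(library_score = 0.95, is_single_candidate = TRUE,
                       candidate_count = 1L), "2a"),
    # same score but several candidates drops to 3a
    list(make_evidence(library_score = 0.95, is_single_candidate = FALSE,
                       candidate_count = 3L), "3a"),
    list(make_evidence(library_score = 0.5), "3a"),
    # > 3 fragments matching with a poor score
    list(make_evidence(library_score = 0.2, n_matched_fragments = 5L), "3b"),
    # fewer than 3 fragments, all of them matching
    list(make_evidence(n_query_peaks = 2L, all_matched = TRUE), "3b"),
    list(make_evidence(ann_sim_comp = 0.8), "3c"),
    list(make_evidence(has_top_formula = TRUE, ann_sim_form = 0.9,
                       iso_score = 0.6, gap_iso = Inf, gap_ann = Inf), "4a"),
    list(make_evidence(has_top_formula = TRUE, iso_score = 0.95,
                       gap_iso = 0.35), "4b"),
    # iso gap below 0.2 is not enough for 4b
    list(make_evidence(has_top_formula = TRUE, iso_score = 0.95,
                       gap_iso = 0.1), "5"),
    list(make_evidence(), "5"))
  for (cs in cases)
    expect_identical(assign_level_suspect(cs[[1]])$value, cs[[2]])
})

test_that("the non-target formula/library cascade respects its score bands", {
  cases <- list(
    list(make_evidence(library_score = 0.95), "2a"),
    list(make_evidence(library_score = 0.8), "3a"),
    list(make_evidence(library_score = 0.9), "3a"),   # 0.9 inclusive to 3a
    list(make_evidence(library_score = 0.5), "3b"),
    list(make_evidence(library_score = 0.4), "5"),    # band is (0.4, 0.7]
    list(make_evidence(has_top_formula = TRUE, ann_sim_form = 0.75,
                       iso_score = 0.55, gap_iso = 0.3, gap_ann = 0.25), "4a"),
    list(make_evidence(), "5"))
  for (cs in cases)
    expect_identical(assign_level_nt_patroon(cs[[1]])$value, cs[[2]])
})

test_that("the non-target dot-product cascade matches every rule cell", {
  base <- list(is_single_candidate = TRUE, candidate_count = 1L,
               n_matched_fragments = 4L, dot_product = 85,
               fragment_presence = 80, structure_known = TRUE)
  ev <- function(...) do.call(make_evidence, utils::modifyList(base, list(...)))
  cases <- list(
    list(ev(), "2a"),
    list(ev(structure_known = FALSE), "2b"),
    list(ev(dot_product = 60, n_matched_fragments = 3L), "3a"),
    list(ev(n_matched_fragments = 2L), "3b"),
    list(ev(n_matched_fragments = 2L, structure_known = FALSE), "3c"),
    list(ev(dot_product = 40), "4a"),
    list(ev(fragment_presence = 40), "4a"),
    # boundaries of the printed ranges are inclusive
    list(ev(dot_product = 70, fragment_presence = 50, n_matched_fragments = 3L), "2a"),
    list(ev(dot_product = 50, n_matched_fragments = 2L), "3b"),
    list(make_evidence(), "5"))
  for (cs in cases)
    expect_identical(assign_level_nt_msdial(cs[[1]])$value, cs[[2]])
})

test_that("every evidence row receives exactly one level per scheme", {
  set.seed(701)
  draw_ev <- function() {
    make_evidence(
      library_score = sample(c(NA, runif(1)), 1),
      dot_product = sample(c(NA, runif(1, 0, 100)), 1),
      fragment_presence = sample(c(NA, runif(1, 0, 100)), 1),
      n_matched_fragments = sample(c(NA, 0:6), 1),
      n_query_peaks = sample(c(NA, 1:8), 1),
      all_matched = sample(c(NA, TRUE, FALSE), 1),
      is_single_candidate = sample(c(NA, TRUE, FALSE), 1),
      structure_known = sample(c(NA, TRUE, FALSE), 1),
      has_top_formula = sample(c(TRUE, FALSE), 1),
      iso_score = sample(c(NA, runif(1)), 1),
      ann_sim_form = sample(c(NA, runif(1)), 1),
      ann_sim_comp = sample(c(NA, runif(1)), 1),
      gap_iso = sample(c(NA, Inf, runif(1, 0, 0.5)), 1),
      gap_ann = sample(c(NA, Inf, runif(1, 0, 0.5)), 1))
  }
  evs <- do.call(rbind, replicate(120, draw_ev(), simplify = FALSE))
  evs$feature_id <- sprintf("F%03d", seq_len(nrow(evs)))
  for (s in c("suspect_patroon", "nt_patroon", "nt_msdial")) {
    lv <- assign_levels(evs, s)
    expect_equal(nrow(lv), nrow(evs))
    expect_true(all(lv$level %in% c("2a", "2b", "3a", "3b", "3c", "4a", "4b", "5")))
    expect_true(all(nzchar(lv$fired_rule)))
    # order determinism: rerunning yields identical assignments
    expect_identical(assign_levels(evs, s), lv)
  }
})

test_that("raising the library score never worsens the suspect-scheme level", {
  set.seed(702)
  for (i in 1:80) {
    e <- make_evidence(
      library_score = runif(1),
      n_matched_fragments = sample(0:6, 1),
      n_query_peaks = sample(1:8, 1),
      all_matched = sample(c(TRUE, FALSE), 1),
      is_single_candidate = sample(c(TRUE, FALSE), 1),
      has_top_formula = sample(c(TRUE, FALSE), 1),
      iso_score = runif(1), ann_sim_form = runif(1), ann_sim_comp = runif(1),
      gap_iso = runif(1, 0, 0.5), gap_ann = runif(1, 0, 0.5))
    lo <- level_rank(assign_level_suspect(e)$value)
    e$library_score <- min(1, e$library_score + runif(1, 0, 1))
    hi <- level_rank(assign_level_suspect(e)$value)
    expect_lte(hi, lo)
  }
})
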