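# Identification-confidence rule engine: three rule cascades mapping
# annotation evidence to levels 2a-5, one per screening scheme (suspect
# screening, non-target screening with formula/library evidence, and
# non-target screening with dot-product/fragment-presence evidence).
#
# Cascades are evaluated best level first, so a feature receives the best
# level it qualifies for; level 5 ("unknown mass of interest") is the total
# fallback. Range conventions: a range written "0.7-0.9" is (0.7, 0.9];
# "70-100" is [70, 100]; explicit > / >= thresholds are literal. Missing
# evidence never satisfies a rule.

.LEVELS <- c("2a", "2b", "3a", "3b", "3c", "4a", "4b", "5")

## Treat NA (absent evidence) as FALSE.
.tv <- function(x) !is.na(x) & x

.level <- function(value, scheme, fired_rule)
  list(value = value, scheme = scheme, fired_rule = fired_rule)

#' Assign a confidence level under the suspect-screening scheme
#'
#' Cascade: 2a (library score > 0.9 and a single candidate), 3a (library
#' score > 0.4), 3b (more than 3 fragments match, or fewer than 3 fragments
#' in total and all of them match), 3c (ann_sim_comp > 0.7), 4a (top-ranked
#' formula with ann_sim_form >= 0.7, iso score >= 0.5 and both gaps to the
#' next candidate >= 0.2), 4b (top-ranked formula with iso score > 0.9 and
#' iso gap > 0.2), else 5.
#'
#' @param e One evidence row (list or one-row data frame) as produced by
#'   [assemble_evidence()]; optional fields may be NA.
#' @return List with `value`, `scheme`, `fired_rule`.
#' @export
assign_level_suspect <- function(e) {
  s <- "suspect_patroon"
  if (.tv(e$library_score > 0.9) && .tv(e$is_single_candidate))
    return(.level("2a", s, "library_score > 0.9 & single candidate"))
  if (.tv(e$library_score > 0.4))
    return(.level("3a", s, "library_score > 0.4"))
  if (.tv(e$n_matched_fragments > 3) ||
      (.tv(e$n_query_peaks < 3) && .tv(e$all_matched)))
    return(.level("3b", s, "> 3 fragments match | < 3 fragments all match"))
  if (.tv(e$ann_sim_comp > 0.7))
    return(.level("3c", s, "ann_sim_comp > 0.7"))
  if (.tv(e$has_top_formula) && .tv(e$ann_sim_form >= 0.7) &&
      .tv(e$iso_score >= 0.5) && .tv(e$gap_iso >= 0.2) && .tv(e$gap_ann >= 0.2))
    return(.level("4a", s, "top formula, ann_sim_form >= 0.7, iso >= 0.5, gaps >= 0.2"))
  if (.tv(e$has_top_formula) && .tv(e$iso_score > 0.9) && .tv(e$gap_iso > 0.2))
    return(.level("4b", s, "top formula, iso > 0.9, iso gap > 0.2"))
  .level("5", s, "unknown mass of interest")
}

#' Assign a confidence level under the non-target formula/library scheme
#'
#' Cascade: 2a (library score > 0.9), 3a (0.7 < score <= 0.9), 3b
#' (0.4 < score <= 0.7), 4a (top-ranked formula with ann_sim_form >= 0.7,
#' iso score >= 0.5 and gaps >= 0.2), else 5.
#'
#' @inheritParams assign_level_suspect
#' @return List with `value`, `scheme`, `fired_rule`.
#' @export
assign_level_nt_patroon <- function(e) {
  s <- "nt_patroon"
  if (.tv(e$library_score > 0.9))
    return(.level("2a", s, "library_score > 0.9"))
  if (.tv(e$library_score > 0.7) && .tv(e$library_score <= 0.9))
    return(.level("3a", s, "library_score 0.7-0.9"))
  if (.tv(e$library_score > 0.4) && .tv(e$library_score <= 0.7))
    return(.level("3b", s, "library_score 0.4-0.7"))
  if (.tv(e$has_top_formula) && .tv(e$ann_sim_form >= 0.7) &&
      .tv(e$iso_score >= 0.5) && .tv(e$gap_iso >= 0.2) && .tv(e$gap_ann >= 0.2))
    return(.level("4a", s, "top formula, ann_sim_form >= 0.7, iso >= 0.5, gaps >= 0.2"))
  .level("5", s, "unknown mass of interest")
}

#' Assign a confidence level under the non-target dot-product scheme
#'
#' Cascade: 2a (single candidate, >= 3 matched fragments, dot product in
#' [70, 100], fragment presence in [50, 100], structure known in library),
#' 2b (same with structure unknown), 3a (>= 3 matched fragments, dot in
#' [50, 70), presence >= 50), 3b (< 3 matched fragments, dot in [50, 100],
#' presence >= 50, structure known), 3c (same with structure unknown), 4a
#' (dot < 50 and/or presence < 50), else 5. Features without any library
#' match fall through to 5.
#'
#' @inheritParams assign_level_suspect
#' @return List with `value`, `scheme`, `fired_rule`.
#' @export
assign_level_nt_msdial <- function(e) {
  s <- "nt_msdial"
  dot_hi <- .tv(e$dot_product >= 70) && .tv(e$dot_product <= 100)
  dot_mid <- .tv(e$dot_product >= 50) && .tv(e$dot_product < 70)
  dot_any <- .tv(e$dot_product >= 50) && .tv(e$dot_product <= 100)
  pres <- .tv(e$fragment_presence >= 50) && .tv(e$fragment_presence <= 100)
  frag3 <- .tv(e$n_matched_fragments >= 3)
  if (.tv(e$is_single_candidate) && frag3 && dot_hi && pres && .tv(e$structure_known))
    return(.level("2a", s, "single candidate, >= 3 fragments, dot 70-100, presence 50-100"))
  if (.tv(e$is_single_candidate) && frag3 && dot_hi && pres && .tv(!e$structure_known))
    return(.level("2b", s, "as 2a but structure unknown in library"))
  if (frag3 && dot_mid && pres)
    return(.level("3a", s, ">= 3 fragments, dot 50-70, presence 50-100"))
  if (.tv(e$n_matched_fragments < 3) && dot_any && pres && .tv(e$structure_known))
    return(.level("3b", s, "< 3 fragments, dot 50-100, presence 50-100"))
  if (.tv(e$n_matched_fragments < 3) && dot_any && pres && .tv(!e$structure_known))
    return(.level("3c", s, "as 3b but structure unknown in library"))
  if (.tv(e$dot_product < 50) || .tv(e$fragment_presence < 50))
    return(.level("4a", s, "dot < 50 and/or presence < 50"))
  .level("5", s, "unknown mass of interest")
}

#' Assign confidence levels for every evidence row
#'
#' @param evidence Data frame from [assemble_evidence()].
#' @param scheme One of `"suspect_patroon"`, `"nt_patroon"`, `"nt_msdial"`.
#' @return Data frame with `feature_id`, `scheme`, `level`, `fired_rule`.
#' @export
assign_levels <- function(evidence, scheme = c("suspect_patroon", "nt_patroon",
                                               "nt_msdial")) {
  scheme <- match.arg(scheme)
  fn <- switch(scheme,
               suspect_patroon = assign_level_suspect,
               nt_patroon = assign_level_nt_patroon,
               nt_msdial = assign_level_nt_msdial)
  res <- lapply(seq_len(nrow(evidence)), function(i) fn(evidence[i, , drop = FALSE]))
  data.frame(feature_id = evidence$feature_id, scheme = scheme,
             level = vapply(res, `[[`, character(1), "value"),
             fired_rule = vapply(res, `[[`, character(1), "fired_rule"),
             stringsAsFactors = FALSE)
}
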