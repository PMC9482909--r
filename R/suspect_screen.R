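# Suspect screening: match features against suspect lists by neutral mass +
# adduct within a ppm tolerance, and assemble the per-feature annotation
# evidence consumed by the confidence rule engine.

.DEFAULT_ADDUCTS <- c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M]+", "[M-H]-", "[M+HCOO]-")

#' Screen features against suspect lists
#'
#' For every feature and every suspect, each adduct whose charge sign is
#' consistent with the feature's ESI mode is tested; a hit is recorded when
#' the ppm error between the feature m/z and the theoretical adduct m/z is at
#' most `tol_ppm`. All hits are retained: a feature may hit several suspects
#' and several lists. Retention time plays no role in matching (suspect lists
#' carry no RT); it is carried through for reporting only.
#'
#' @param fs A [feature_set()].
#' @param suspects Data frame from [read_suspect_list()] (several lists may
#'   be row-bound).
#' @param adducts Character vector of adduct names to consider.
#' @param tol_ppm Mass tolerance in ppm.
#' @return Data frame of `SuspectHit` rows: `feature_id`, `mz`, `rt`,
#'   `esi_mode`, `name`, `formula`, `neutral_mass`, `inchikey`, `list_code`,
#'   `adduct`, `theoretical_mz`, `ppm_error`.
#' @export
screen_suspects <- function(fs, suspects, adducts = .DEFAULT_ADDUCTS, tol_ppm = 5) {
  if (!nrow(suspects)) stop("suspect list is empty")
  hits <- list()
  for (ad in adducts) {
    a <- parse_adduct(ad)
    mode <- if (a$charge > 0) "+" else "-"
    fidx <- which(fs$features$esi_mode == mode)
    if (!length(fidx)) next
    theo <- (suspects$neutral_mass + a$mass_shift - a$charge * .ELECTRON_MASS) /
      abs(a$charge)
    for (i in fidx) {
      dppm <- ppm_error(fs$features$mz[i], theo)
      sj <- which(abs(dppm) <= tol_ppm)
      if (!length(sj)) next
      hits[[length(hits) + 1L]] <- data.frame(
        feature_id = fs$features$feature_id[i],
        mz = fs$features$mz[i], rt = fs$features$rt[i],
        esi_mode = fs$features$esi_mode[i],
        name = suspects$name[sj], formula = suspects$formula[sj],
        neutral_mass = suspects$neutral_mass[sj],
        inchikey = suspects$inchikey[sj], list_code = suspects$list_code[sj],
        adduct = a$name, theoretical_mz = theo[sj], ppm_error = dppm[sj],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), mz = numeric(0), rt = numeric(0),
                      esi_mode = character(0), name = character(0),
                      formula = character(0), neutral_mass = numeric(0),
                      inchikey = character(0), list_code = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Merge suspect hits across lists
#'
#' Collapses hits to one row per (feature, InChIKey first block) — the
#' 14-character skeleton block, so stereoisomer entries merge — with the
#' union of list codes and the smallest |ppm error|. Hits without an InChIKey
#' fall back to the case-folded suspect name as the merge key.
#'
#' @param hits Data frame from [screen_suspects()].
#' @return Data frame with one row per (feature_id, key): `feature_id`,
#'   `name`, `key`, `list_codes` (comma-joined, sorted), `n_lists`,
#'   `n_duplicates`, `adduct`, `ppm_error`.
#' @export
merge_hits_across_lists <- function(hits) {
  if (!nrow(hits))
    return(data.frame(feature_id = character(0), name = character(0),
                      key = character(0), list_codes = character(0),
                      n_lists = integer(0), n_duplicates = integer(0),
                      adduct = character(0), ppm_error = numeric(0),
                      stringsAsFactors = FALSE))
  key <- ifelse(!is.na(hits$inchikey) & nzchar(hits$inchikey),
                substr(hits$inchikey, 1L, 14L), tolower(hits$name))
  grp <- paste(hits$feature_id, key, sep = "\r")
  rows <- lapply(split(seq_len(nrow(hits)), grp), function(ii) {
    h <- hits[ii, , drop = FALSE]
    best <- which.min(abs(h$ppm_error))
    data.frame(feature_id = h$feature_id[1], name = h$name[best],
               key = substr(key[ii[1]], 1L, 14L),
               list_codes = paste(sort(unique(h$list_code)), collapse = ","),
               n_lists = length(unique(h$list_code)),
               n_duplicates = nrow(h) - length(unique(h$list_code)),
               adduct = h$adduct[best], ppm_error = h$ppm_error[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_id, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble annotation evidence for every feature
#'
#' Combines, per feature: the best library search result (dot product,
#' fragment presence, matched-fragment counts, library score, structure
#' flag, candidate count), and formula annotation at the feature's neutral
#' mass (candidate enumeration, isotope score against the observed pattern
#' when present, MS/MS consistency for the top candidates, ranking with
#' gap-to-next values). The neutral mass is derived from the suspect hit's
#' adduct when the feature has one, else from the mode's default adduct
#' (`[M+H]+` / `[M-H]-`).
#'
#' @param fs A [feature_set()].
#' @param hits Suspect hits from [screen_suspects()] (may be empty).
#' @param library List of library spectra (may be empty).
#' @param config Run configuration list, see [default_run_config()].
#' @return Data frame with one `AnnotationEvidence` row per feature:
#'   all score columns (NA when the underlying evidence is absent),
#'   `candidate_count`, `is_single_candidate`, `structure_known`,
#'   `top_formula`, `has_top_formula`, `iso_score`, `ann_sim_form`,
#'   `ann_sim_comp`, `gap_iso`, `gap_ann`, `n_formula_candidates`.
#' @export
assemble_evidence <- function(fs, hits, library, config = default_run_config()) {
  feats <- fs$features
  n <- nrow(feats)
  ev <- data.frame(
    feature_id = feats$feature_id,
    library_score = NA_real_, dot_product = NA_real_,
    fragment_presence = NA_real_, n_matched_fragments = NA_integer_,
    n_query_peaks = NA_integer_, n_matched_query = NA_integer_,
    all_matched = NA, candidate_count = NA_integer_, is_single_candidate = NA,
    structure_known = NA, has_top_formula = FALSE, top_formula = NA_character_,
    formula_ppm = NA_real_, iso_score = NA_real_, ann_sim_form = NA_real_,
    ann_sim_comp = NA_real_, gap_iso = NA_real_, gap_ann = NA_real_,
    n_formula_candidates = 0L, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    fid <- feats$feature_id[i]
    mode <- feats$esi_mode[i]
    ms2 <- fs$ms2[[fid]]
    obs_iso <- fs$iso[[fid]]

    lib <- library_search(feats$mz[i], ms2, library,
                          tol_ppm = config$ms1_tol_ppm, tol_mz = config$ms2_tol_mz,
                          rel_int_floor = config$rel_int_floor)
    lib_dot <- NULL
    if (nrow(lib)) {
      top <- lib[1L, ]
      ev$library_score[i] <- top$library_score
      ev$dot_product[i] <- top$dot_product
      ev$fragment_presence[i] <- top$fragment_presence
      ev$n_matched_fragments[i] <- top$n_matched_fragments
      ev$n_query_peaks[i] <- top$n_query_peaks
      ev$n_matched_query[i] <- top$n_matched_query
      ev$all_matched[i] <- top$n_matched_query == top$n_query_peaks
      ev$structure_known[i] <- top$structure_known
      ev$candidate_count[i] <- nrow(lib)
      if (top$structure_known) lib_dot <- top$dot_product
    }

    fhits <- hits[hits$feature_id == fid, , drop = FALSE]
    adduct <- if (nrow(fhits)) fhits$adduct[which.min(abs(fhits$ppm_error))]
              else if (mode == "+") "[M+H]+" else "[M-H]-"
    neutral <- .neutral_mass_from_mz(feats$mz[i], adduct)
    cand <- tryCatch(
      enumerate_formulas(neutral, tol_ppm = config$ms1_tol_ppm,
                         element_bounds = config$element_bounds),
      error = function(e) NULL)
    if (!is.null(cand) && nrow(cand)) {
      ev$n_formula_candidates[i] <- nrow(cand)
      cand$iso_score <- NA_real_
      if (!is.null(obs_iso)) {
        cand$iso_score <- vapply(cand$formula, function(f) {
          iso_score(obs_iso, isotope_pattern(f, max_peaks = config$iso_max_peaks))
        }, numeric(1))
      }
      cand$ann_sim_form <- NA_real_
      cand$ann_sim_comp <- NA_real_
      if (!is.null(ms2)) {
        # MS/MS consistency is scored for the leading candidates only; the
        # tail of the ppm-ordered list never reaches rank 1.
        key_iso <- ifelse(is.na(cand$iso_score), -Inf, cand$iso_score)
        lead <- order(-key_iso, abs(cand$ppm_error))[seq_len(min(5L, nrow(cand)))]
        for (j in lead) {
          as <- ann_sim(ms2, cand$formula[j], tol_mz = config$ms2_tol_mz,
                        esi_mode = mode, library_dot = lib_dot)
          cand$ann_sim_form[j] <- as$ann_sim_form
          cand$ann_sim_comp[j] <- as$ann_sim_comp
        }
      }
      ranked <- rank_candidates(cand)
      ev$has_top_formula[i] <- TRUE
      ev$top_formula[i] <- ranked$formula[1]
      ev$formula_ppm[i] <- ranked$ppm_error[1]
      ev$iso_score[i] <- ranked$iso_score[1]
      ev$ann_sim_form[i] <- ranked$ann_sim_form[1]
      ev$ann_sim_comp[i] <- ranked$ann_sim_comp[1]
      ev$gap_iso[i] <- ranked$gap_iso[1]
      ev$gap_ann[i] <- ranked$gap_ann[1]
      if (is.na(ev$candidate_count[i])) {
        ev$candidate_count[i] <- nrow(cand)
      }
    }
    if (!is.na(ev$candidate_count[i]))
      ev$is_single_candidate[i] <- ev$candidate_count[i] == 1L
  }
  ev
}
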