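# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation paths they check.

# Best one-to-one peak pairing by exhaustive recursion over all injective
# assignments: maximize match count, then minimize total |delta mz|.
oracle_best_pairing <- function(q, r, tol) {
  best <- list(count = 0L, dist = Inf)
  m <- length(r)
  rec <- function(i, used, count, dist) {
    if (i > length(q)) {
      if (count > best$count || (count == best$count && dist < best$dist))
        best <<- list(count = count, dist = dist)
      return(invisible(NULL))
    }
    rec(i + 1L, used, count, dist)
    for (j in seq_len(m)) {
      if (!used[j] && abs(q[i] - r[j]) <= tol) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L, dist + abs(q[i] - r[j]))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0L, 0)
  if (is.infinite(best$dist)) best$dist <- 0
  best
}

# Nested-loop CHNO formula enumeration with its own mass table and rules.
oracle_enumerate_chno <- function(mass, tol_ppm, cmax, hmax, nmax, omax) {
  am <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
  win <- mass * tol_ppm * 1e-6
  out <- character(0)
  for (nc in 0:cmax) for (nh in 0:hmax) for (nn in 0:nmax) for (no in 0:omax) {
    m <- nc * am["C"] + nh * am["H"] + nn * am["N"] + no * am["O"]
    if (m <= 0 || abs(m - mass) > win) next
    dbe2 <- 2L * nc + 2L + nn - nh
    if (dbe2 < 0L || dbe2 %% 2L != 0L) next
    if (nc > 0 && nh > 0 && (nh / nc < 0.1 || nh / nc > 3.5)) next
    parts <- c(C = nc, H = nh, N = nn, O = no)
    parts <- parts[parts > 0]
    out <- c(out, paste0(names(parts), ifelse(parts == 1, "", parts),
                         collapse = ""))
  }
  sort(out)
}

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_ora_p <- function(hits, pathway_size, universe_size, selected_size) {
  jj <- hits:min(pathway_size, selected_size)
  sum(choose(pathway_size, jj) *
        choose(universe_size - pathway_size, selected_size - jj)) /
    choose(universe_size, selected_size)
}

# Small FeatureSet around an explicit intensity matrix.
make_toy_fs <- function(intensities, design, mz = NULL, esi = "+") {
  n <- nrow(intensities)
  feats <- data.frame(
    feature_id = rownames(intensities),
    mz = if (is.null(mz)) seq(100, 100 + n - 1) else mz,
    rt = seq_len(n), esi_mode = rep(esi, length.out = n),
    lc_mode = "RP", fraction = "polar", stringsAsFactors = FALSE)
  feature_set(feats, intensities, design)
}

# One annotation-evidence row with every field absent unless overridden.
make_evidence <- function(...) {
  ev <- data.frame(
    feature_id = "F1", library_score = NA_real_, dot_product = NA_real_,
    fragment_presence = NA_real_, n_matched_fragments = NA_integer_,
    n_query_peaks = NA_integer_, n_matched_query = NA_integer_,
    all_matched = NA, candidate_count = NA_integer_, is_single_candidate = NA,
    structure_known = NA, has_top_formula = FALSE, top_formula = NA_character_,
    formula_ppm = NA_real_, iso_score = NA_real_, ann_sim_form = NA_real_,
    ann_sim_comp = NA_real_, gap_iso = NA_real_, gap_ann = NA_real_,
    n_formula_candidates = 0L, stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) ev[[k]] <- over[[k]]
  ev
}

level_rank <- function(lv) match(lv, c("2a", "2b", "3a", "3b", "3c", "4a", "4b", "5"))

random_spectrum <- function(n, lo = 50, hi = 500) {
  new_spectrum(sort(runif(n, lo, hi)), runif(n, 1, 100))
}
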