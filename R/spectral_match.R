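# MS/MS library search: peak pairing, cosine dot product (0-100), fragment
# presence (0-100), matched-fragment counts, and the normalized library score
# in [0,1] consumed by the confidence rules.

.spec_peaks <- function(x) {
  if (inherits(x, "spectrum")) return(list(mz = x$mz, intensity = x$intensity))
  if (is.matrix(x) || is.data.frame(x))
    return(list(mz = as.numeric(x[, 1]), intensity = as.numeric(x[, 2])))
  stop("expected a spectrum object or a two-column (mz, intensity) table")
}

#' Pair query and reference peaks one-to-one within a tolerance
#'
#' Finds the one-to-one pairing of query and reference peaks with
#' |delta m/z| <= `tol_mz` that maximizes the number of pairs and, among
#' those, minimizes the total absolute m/z deviation. Because peak lists are
#' sorted, the optimum is attained by a non-crossing pairing and is computed
#' by dynamic programming; it agrees with exhaustive search over all
#' one-to-one pairings.
#'
#' @param query,reference Spectrum objects (or two-column matrices).
#' @param tol_mz Matching tolerance in Da (> 0).
#' @return Data frame with columns `query_idx`, `ref_idx`, `query_mz`,
#'   `ref_mz`, `delta`.
#' @export
match_peaks <- function(query, reference, tol_mz = 0.01) {
  if (tol_mz <= 0) stop("tol_mz must be > 0")
  q <- .spec_peaks(query)$mz
  r <- .spec_peaks(reference)$mz
  n <- length(q); m <- length(r)
  cnt <- matrix(0L, n + 1L, m + 1L)
  dst <- matrix(0, n + 1L, m + 1L)
  mov <- matrix(0L, n + 1L, m + 1L)  # 1 = skip query, 2 = skip ref, 3 = pair
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      bc <- cnt[i, j + 1L]; bd <- dst[i, j + 1L]; bm <- 1L
      if (cnt[i + 1L, j] > bc || (cnt[i + 1L, j] == bc && dst[i + 1L, j] < bd)) {
        bc <- cnt[i + 1L, j]; bd <- dst[i + 1L, j]; bm <- 2L
      }
      d <- abs(q[i] - r[j])
      if (d <= tol_mz) {
        pc <- cnt[i, j] + 1L; pd <- dst[i, j] + d
        if (pc > bc || (pc == bc && pd < bd)) { bc <- pc; bd <- pd; bm <- 3L }
      }
      cnt[i + 1L, j + 1L] <- bc; dst[i + 1L, j + 1L] <- bd; mov[i + 1L, j + 1L] <- bm
    }
  }
  qi <- integer(0); ri <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    mv <- mov[i + 1L, j + 1L]
    if (mv == 3L) { qi <- c(i, qi); ri <- c(j, ri); i <- i - 1L; j <- j - 1L }
    else if (mv == 1L) i <- i - 1L
    else j <- j - 1L
  }
  data.frame(query_idx = qi, ref_idx = ri,
             query_mz = q[qi], ref_mz = r[ri], delta = q[qi] - r[ri])
}

#' Spectral dot product on the 0-100 scale
#'
#' 100 times the cosine similarity between square-root-scaled intensity
#' vectors laid out over the union of matched and unmatched peak slots.
#' Symmetric in its arguments and invariant to rescaling either spectrum.
#'
#' @inheritParams match_peaks
#' @return Score in [0, 100]; identical spectra score 100, spectra with no
#'   shared peaks score 0.
#' @export
dot_product_score <- function(query, reference, tol_mz = 0.01) {
  qp <- .spec_peaks(query); rp <- .spec_peaks(reference)
  if (!length(qp$mz) || !length(rp$mz)) stop("both spectra must be non-empty")
  pairs <- match_peaks(query, reference, tol_mz)
  num <- sum(sqrt(qp$intensity[pairs$query_idx] * rp$intensity[pairs$ref_idx]))
  den <- sqrt(sum(qp$intensity) * sum(rp$intensity))
  if (den == 0) return(0)
  100 * num / den
}

#' Fragment presence percentage
#'
#' Percentage of reference peaks at or above a relative intensity floor that
#' are matched by a query peak within `tol_mz`.
#'
#' @inheritParams match_peaks
#' @param rel_int_floor Relative intensity floor as a fraction of the
#'   reference base peak (default 0.01); reference peaks below it are
#'   excluded from the denominator.
#' @return Percentage in [0, 100].
#' @export
fragment_presence <- function(query, reference, tol_mz = 0.01, rel_int_floor = 0.01) {
  rp <- .spec_peaks(reference)
  above <- which(rp$intensity >= rel_int_floor * max(rp$intensity))
  if (!length(above)) stop("reference has no peak above the intensity floor")
  pairs <- match_peaks(query, reference, tol_mz)
  100 * sum(pairs$ref_idx %in% above) / length(above)
}

#' Count matched reference fragments
#'
#' Number of matched reference peaks with relative intensity at or above
#' `rel_int_floor` of the reference base peak, so that ">= 3 ion fragments
#' matching" cannot be satisfied by noise peaks.
#'
#' @inheritParams fragment_presence
#' @return Integer count.
#' @export
count_matched_fragments <- function(query, reference, tol_mz = 0.01, rel_int_floor = 0.01) {
  rp <- .spec_peaks(reference)
  above <- which(rp$intensity >= rel_int_floor * max(rp$intensity))
  pairs <- match_peaks(query, reference, tol_mz)
  sum(pairs$ref_idx %in% above)
}

#' Search an MS/MS library for candidates of a feature
#'
#' Candidates are library spectra whose precursor m/z lies within
#' `tol_ppm` of the feature m/z. Each candidate is scored (dot product,
#' fragment presence, matched-fragment count); the library score is the
#' normalized dot product in [0, 1], a surrogate that preserves the ordering
#' and range of a MoNA-style match score. Candidates are ranked by library
#' score descending, ties broken by |precursor delta ppm| ascending and then
#' by library record index.
#'
#' @param mz Feature m/z (Th).
#' @param ms2 The feature's MS/MS spectrum, or NULL (yields an empty result:
#'   the feature proceeds as mass-only).
#' @param library List of library spectrum objects.
#' @param tol_ppm Precursor tolerance in ppm (default 5).
#' @param tol_mz MS/MS peak tolerance in Da (default 0.01).
#' @param rel_int_floor Relative intensity floor for fragment counting.
#' @return Data frame of `SpectralMatch` rows: `library_name`,
#'   `library_index`, `precursor_ppm`, `dot_product`, `fragment_presence`,
#'   `n_matched_fragments`, `n_query_peaks`, `n_matched_query`,
#'   `library_score`, `structure_known`, `candidate_rank`.
#' @export
library_search <- function(mz, ms2, library, tol_ppm = 5, tol_mz = 0.01,
                           rel_int_floor = 0.01) {
  empty <- data.frame(library_name = character(0), library_index = integer(0),
                      precursor_ppm = numeric(0), dot_product = numeric(0),
                      fragment_presence = numeric(0), n_matched_fragments = integer(0),
                      n_query_peaks = integer(0), n_matched_query = integer(0),
                      library_score = numeric(0), structure_known = logical(0),
                      candidate_rank = integer(0), stringsAsFactors = FALSE)
  if (is.null(ms2) || !length(library)) return(empty)
  prec <- vapply(library, function(s) s$precursor_mz %||% NA_real_, numeric(1))
  dppm <- ppm_error(mz, ifelse(is.na(prec) | prec <= 0, Inf, prec))
  cand <- which(!is.na(prec) & abs(dppm) <= tol_ppm)
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(k) {
    ref <- library[[k]]
    pairs <- match_peaks(ms2, ref, tol_mz)
    data.frame(
      library_name = ref$name %||% paste0("record_", k), library_index = k,
      precursor_ppm = dppm[k],
      dot_product = dot_product_score(ms2, ref, tol_mz),
      fragment_presence = fragment_presence(ms2, ref, tol_mz, rel_int_floor),
      n_matched_fragments = count_matched_fragments(ms2, ref, tol_mz, rel_int_floor),
      n_query_peaks = length(ms2$mz),
      n_matched_query = length(unique(pairs$query_idx)),
      structure_known = isTRUE(ref$structure_known),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$library_score <- out$dot_product / 100
  o <- order(-out$library_score, abs(out$precursor_ppm), out$library_index)
  out <- out[o, , drop = FALSE]
  out$candidate_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
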