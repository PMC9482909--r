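# Candidate molecular formula enumeration for a neutral mass, isotope-pattern
# scoring, and MS/MS-consistency scores quantifying how much of a spectrum a
# formula candidate can explain.

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Exhaustively searches element-count combinations within `element_bounds`
#' whose monoisotopic mass lies within `tol_ppm` of `neutral_mass`, filtered
#' by chemical plausibility rules: integer ring-plus-double-bond equivalents
#' >= 0 and H/C within `hc_range` (the H/C rule applies only when both carbon
#' and hydrogen are present, so bare carbon clusters remain valid).
#'
#' The search grid is built element by element (heaviest first) with mass
#' pruning at every step; hydrogen is solved last from the residual mass.
#' Bounds whose pruned grid still exceeds `max_combinations` raise an error
#' instructing tighter bounds.
#'
#' @param neutral_mass Target neutral monoisotopic mass (Da, > 0).
#' @param tol_ppm Mass tolerance in ppm.
#' @param element_bounds Named vector of maximum element counts; must cover at
#'   least C, H, N, O. Defaults span the small-molecule scan range.
#' @param hc_range Allowed H/C ratio range.
#' @param max_combinations Grid-size guard.
#' @return Data frame with columns `formula` (Hill string), `mass`,
#'   `ppm_error`, ordered by |ppm_error| then formula.
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm = 5,
                               element_bounds = c(C = 40, H = 80, N = 6, O = 12,
                                                  S = 3, P = 2, Cl = 3, F = 6),
                               hc_range = c(0.1, 3.5),
                               max_combinations = 1e6) {
  if (neutral_mass <= 0) stop("neutral_mass must be > 0")
  if (!all(c("C", "H", "N", "O") %in% names(element_bounds)))
    stop("element_bounds must cover at least C, H, N, O")
  bad <- setdiff(names(element_bounds), names(.MONO_MASS))
  if (length(bad)) stop("unsupported element(s) in bounds: ", paste(bad, collapse = ", "))
  win <- neutral_mass * tol_ppm * 1e-6
  mmin <- neutral_mass - win; mmax <- neutral_mass + win
  mH <- .MONO_MASS[["H"]]

  elems <- setdiff(names(element_bounds), "H")
  elems <- elems[order(-.MONO_MASS[elems])]
  grid <- matrix(0L, 1L, 0L)
  mass <- 0
  for (el in elems) {
    k <- 0:element_bounds[[el]]
    nb <- length(k); ng <- nrow(grid)
    newmass <- rep(mass, times = nb) + rep(k * .MONO_MASS[[el]], each = ng)
    keep <- newmass <= mmax + element_bounds[["H"]] * mH
    if (sum(keep) > max_combinations)
      stop("element bounds produce more than ", format(max_combinations, scientific = FALSE),
           " candidate combinations; tighten the bounds")
    grid <- cbind(grid[rep(seq_len(ng), times = nb)[keep], , drop = FALSE],
                  rep(k, each = ng)[keep])
    colnames(grid)[ncol(grid)] <- el
    mass <- newmass[keep]
  }

  # Solve hydrogen from the residual mass; the ppm window is far narrower
  # than one hydrogen, so at most one neighbor on either side can qualify.
  h0 <- round((neutral_mass - mass) / mH)
  res <- list()
  mono <- function(cn) if (cn %in% colnames(grid)) grid[, cn] else rep(0L, nrow(grid))
  Cc <- mono("C"); Nn <- mono("N"); Pp <- mono("P")
  monoval <- mono("F") + mono("Cl") + mono("Br") + mono("Na")
  for (dh in -1:1) {
    h <- h0 + dh
    total <- mass + h * mH
    ok <- h >= 0 & h <= element_bounds[["H"]] &
      abs(total - neutral_mass) <= win & total > 0
    if (!any(ok)) next
    dbe2 <- 2L * Cc + 2L + Nn + Pp - h - monoval   # 2 * RDBE
    ok <- ok & dbe2 >= 0 & dbe2 %% 2L == 0L
    hc_applies <- Cc > 0L & h > 0L
    ok <- ok & (!hc_applies | (h / pmax(Cc, 1L) >= hc_range[1] &
                                 h / pmax(Cc, 1L) <= hc_range[2]))
    if (!any(ok)) next
    idx <- which(ok)
    res[[length(res) + 1L]] <- data.frame(
      formula = vapply(idx, function(i) {
        cnts <- c(grid[i, ], H = h[i])
        formula_string(cnts[cnts > 0])
      }, character(1)),
      mass = total[idx], stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out$ppm_error <- ppm_error(neutral_mass, out$mass)
  out <- out[!duplicated(out$formula), , drop = FALSE]
  out <- out[order(abs(out$ppm_error), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isotope-pattern similarity score
#'
#' `1 - mean(|observed - theoretical|)` over the aligned A..A+k envelope
#' peaks, where k+1 is the shorter pattern length, clipped to [0, 1]. Both
#' patterns must be base-peak normalized; identical patterns score 1.
#'
#' @param observed,theoretical Isotope patterns as data frames with columns
#'   `mass` and `abundance` (base peak = 1), e.g. from [isotope_pattern()].
#' @return Score in [0, 1].
#' @export
iso_score <- function(observed, theoretical) {
  if (!nrow(observed) || !nrow(theoretical)) stop("patterns must be non-empty")
  k <- min(nrow(observed), nrow(theoretical))
  s <- 1 - mean(abs(observed$abundance[seq_len(k)] - theoretical$abundance[seq_len(k)]))
  min(max(s, 0), 1)
}

## Mass set of all sub-formulas of a candidate (element-wise <= counts),
## empty composition excluded. Returns a sorted numeric vector.
.subformula_masses <- function(counts) {
  masses <- 0
  for (el in names(counts)) {
    masses <- as.vector(outer(masses, (0:counts[[el]]) * .MONO_MASS[[el]], `+`))
  }
  sort(masses[masses > 0])
}

#' MS/MS consistency of a spectrum with a formula candidate
#'
#' A query peak is "explainable" when it can be read as a sub-formula of the
#' candidate (element-wise bounded by the candidate counts) ionized for the
#' given ESI mode — protonated/deprotonated or electron-loss — with a
#' hydrogen latitude of +/- 1 H, within `tol_mz`. `ann_sim_form` is the
#' normalized dot product between the query spectrum and its explainable
#' sub-spectrum, i.e. the square root of the explainable intensity fraction.
#' `ann_sim_comp` additionally folds in library structure evidence when
#' available: `min(ann_sim_form, library_dot / 100)`.
#'
#' @param query A spectrum object (>= 1 peak).
#' @param candidate Candidate formula (string or named counts).
#' @param tol_mz Fragment tolerance in Da.
#' @param esi_mode `"+"` or `"-"`.
#' @param library_dot Optional library dot product (0-100) of the best
#'   structure candidate; NULL when no structure evidence exists.
#' @return List with `ann_sim_form`, `ann_sim_comp` and the logical vector
#'   `explained` (one element per query peak).
#' @export
ann_sim <- function(query, candidate, tol_mz = 0.01, esi_mode = "+",
                    library_dot = NULL) {
  qp <- .spec_peaks(query)
  if (!length(qp$mz)) stop("query spectrum must have at least one peak")
  counts <- .as_counts(candidate)
  masses <- .subformula_masses(counts)
  mH <- .MONO_MASS[["H"]]
  shifts <- if (esi_mode == "+") {
    c(.PROTON_MASS, -.ELECTRON_MASS)
  } else {
    -.PROTON_MASS
  }
  shifts <- as.vector(outer(shifts, c(-mH, 0, mH), `+`))
  explained <- vapply(qp$mz, function(pk) {
    for (s in shifts) {
      target <- pk - s
      i <- findInterval(target, masses)
      if ((i >= 1L && abs(masses[i] - target) <= tol_mz) ||
          (i < length(masses) && abs(masses[i + 1L] - target) <= tol_mz))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  total <- sum(qp$intensity)
  form <- if (total == 0) 0 else sqrt(sum(qp$intensity[explained]) / total)
  comp <- if (is.null(library_dot) || is.na(library_dot)) form
          else min(form, library_dot / 100)
  list(ann_sim_form = form, ann_sim_comp = comp, explained = explained)
}

#' Rank formula candidates
#'
#' Sorts candidates by isotope score (descending, missing scores last), then
#' |ppm error| ascending, then `ann_sim_form` descending, with final ties
#' broken by the Hill formula string so ranking is a total order independent
#' of input order. Gap-to-next-candidate columns (`gap_iso`, `gap_ann`) feed
#' the "0.2 higher than the next candidate" confidence tests; a single
#' candidate has infinite gaps.
#'
#' @param candidates Data frame with columns `formula`, `ppm_error` and
#'   optionally `iso_score`, `ann_sim_form`, `ann_sim_comp` (NA allowed).
#' @return The same rows ordered with `rank` (1 = best), `gap_iso`, `gap_ann`.
#' @export
rank_candidates <- function(candidates) {
  if (!nrow(candidates)) stop("at least one candidate required")
  for (col in c("iso_score", "ann_sim_form", "ann_sim_comp"))
    if (is.null(candidates[[col]])) candidates[[col]] <- NA_real_
  key_iso <- ifelse(is.na(candidates$iso_score), -Inf, candidates$iso_score)
  key_ann <- ifelse(is.na(candidates$ann_sim_form), -Inf, candidates$ann_sim_form)
  o <- order(-key_iso, abs(candidates$ppm_error), -key_ann, candidates$formula)
  out <- candidates[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  nxt <- function(v) {
    if (nrow(out) == 1L) return(Inf)
    v2 <- ifelse(is.na(v), -Inf, v)
    gaps <- c(v2[-length(v2)] - v2[-1L], Inf)
    gaps[is.nan(gaps)] <- NA_real_  # both scores missing: gap undefined
    gaps
  }
  out$gap_iso <- nxt(out$iso_score)
  out$gap_ann <- nxt(out$ann_sim_form)
  rownames(out) <- NULL
  out
}
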