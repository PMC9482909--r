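# MetaboAnalyst-style statistics: IQR filtering, sum normalization, Pareto
# scaling, Welch t-tests and fold changes, NIPALS PLS-DA (optionally with one
# orthogonal component removed first) with VIP scores, and the three-way
# significance rule p < 0.1 AND (FC > 2 OR FC < 0.5) AND VIP > 1.

#' Filter features by interquartile range
#'
#' Features are ranked by their IQR across the given samples and the least
#' variable fraction is dropped according to the size ladder: 0% below 250
#' features, 5% below 500, 10% below 1000, 25% below 2000, 40% otherwise.
#' Ties (including constant features, IQR 0) are broken by feature id so the
#' filter is deterministic.
#'
#' @param mat Numeric matrix, features x samples, rownames = feature ids.
#' @param ladder Data frame with columns `below` (feature-count upper bound)
#'   and `frac` (fraction dropped); the first matching row applies.
#' @return List with `matrix` (retained rows, input order preserved),
#'   `dropped` (ids) and `frac` (fraction applied).
#' @export
iqr_filter <- function(mat,
                       ladder = data.frame(below = c(250, 500, 1000, 2000, Inf),
                                           frac = c(0, 0.05, 0.10, 0.25, 0.40))) {
  n <- nrow(mat)
  if (n < 10L) stop("IQR filter expects at least 10 features")
  frac <- ladder$frac[which(n < ladder$below)[1]]
  k <- floor(frac * n)
  if (k == 0L) return(list(matrix = mat, dropped = character(0), frac = frac))
  iqr <- apply(mat, 1L, stats::IQR)
  o <- order(iqr, rownames(mat))
  dropped <- rownames(mat)[o[seq_len(k)]]
  list(matrix = mat[!rownames(mat) %in% dropped, , drop = FALSE],
       dropped = dropped, frac = frac)
}

#' Sum normalization followed by Pareto scaling
#'
#' Each sample column is divided by its total and multiplied by the mean
#' total (so normalization is idempotent), then each feature row is centered
#' and divided by the square root of its standard deviation (Pareto).
#' Constant rows (sd 0) scale to all zeros. The normalized-but-unscaled
#' matrix is retained for fold-change computation.
#'
#' @param mat Numeric matrix, features x samples; no all-zero sample allowed.
#' @return List with `normalized` (sum-normalized) and `scaled` (Pareto).
#' @export
normalize_and_scale <- function(mat) {
  totals <- colSums(mat)
  if (any(totals == 0))
    stop("all-zero sample(s): ", paste(colnames(mat)[totals == 0], collapse = ", "))
  normalized <- sweep(mat, 2L, totals, "/") * mean(totals)
  mu <- rowMeans(normalized)
  sdev <- apply(normalized, 1L, stats::sd)
  scaled <- (normalized - mu) / ifelse(sdev > 0, sqrt(sdev), 1)
  scaled[sdev == 0, ] <- 0
  list(normalized = normalized, scaled = scaled)
}

#' Per-feature fold change and Welch t-test p-value
#'
#' Fold change is the ratio of group means on the normalized-but-unscaled
#' intensities (`groups[1]` over `groups[2]`); the two-sided p-value comes
#' from a Welch (unequal-variance) t-test on the scaled values. Features
#' whose denominator group mean is zero get an undefined fold change (NA,
#' with a warning).
#'
#' @param normalized,scaled Matrices from [normalize_and_scale()].
#' @param design Named group vector.
#' @param groups Length-2 character vector: numerator and denominator groups
#'   (default PD over Ctrl); each needs >= 3 samples.
#' @return Data frame with `feature_id`, `fold_change`, `p_value`.
#' @export
univariate_stats <- function(normalized, scaled, design, groups = c("PD", "Ctrl")) {
  g1 <- names(design)[design == groups[1]]
  g2 <- names(design)[design == groups[2]]
  if (length(g1) < 3L || length(g2) < 3L)
    stop("both groups need >= 3 samples (", groups[1], ": ", length(g1),
         ", ", groups[2], ": ", length(g2), ")")
  m1 <- rowMeans(normalized[, g1, drop = FALSE])
  m2 <- rowMeans(normalized[, g2, drop = FALSE])
  fc <- ifelse(m2 > 0, m1 / m2, NA_real_)
  if (anyNA(fc))
    warning(sum(is.na(fc)), " feature(s) with zero denominator mean: fold change undefined")
  p <- vapply(seq_len(nrow(scaled)), function(i) {
    x <- scaled[i, g1]; y <- scaled[i, g2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate zero-variance feature: identical groups are uninformative,
      # separated groups are unambiguously different
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  data.frame(feature_id = rownames(normalized), fold_change = fc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

## NIPALS PLS1: X (samples x features, columns centered), y centered.
## Returns per-component weights and explained-y sums of squares.
.nipals_pls1 <- function(X, y, ncomp) {
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5)
      stop("singular or constant data matrix: PLS weights vanish")
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    pvec <- crossprod(X, t) / tt
    q <- sum(y * t) / tt
    X <- X - t %*% t(pvec)
    y <- y - q * t
    W[, a] <- w
    ssy[a] <- q^2 * tt
  }
  list(W = W, ssy = ssy)
}

#' PLS-DA / O-PLS-DA VIP scores
#'
#' Fits a NIPALS PLS1 model of the two-class membership (coded -1/+1,
#' centered) on the scaled feature matrix. With `orthogonal = TRUE` one
#' orthogonal component is removed first (single-component O-PLS) and VIP is
#' computed on the predictive component(s):
#' `VIP_j = sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a))`, which satisfies
#' `sum(VIP^2) = p` (the number of features).
#'
#' @param scaled Matrix from [normalize_and_scale()], features x samples.
#' @param design Named group vector.
#' @param groups Length-2 character vector of class labels.
#' @param n_components Number of predictive components (default 1).
#' @param orthogonal Remove one orthogonal component first (default TRUE).
#' @return Named numeric vector of VIP scores, one per feature.
#' @export
plsda_vip <- function(scaled, design, groups = c("PD", "Ctrl"),
                      n_components = 1L, orthogonal = TRUE) {
  samples <- names(design)[design %in% groups]
  if (length(unique(design[samples])) != 2L) stop("exactly two classes required")
  X <- t(scaled[, samples, drop = FALSE])
  y <- ifelse(design[samples] == groups[1], 1, -1)
  y <- y - mean(y)
  X <- sweep(X, 2L, colMeans(X))
  if (n_components < 1L || n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components must be in [1, min(n_samples - 1, n_features)]")
  if (orthogonal && nrow(X) > 2L) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) stop("singular or constant data matrix")
    w <- w / nw
    t <- X %*% w
    pvec <- crossprod(X, t) / sum(t^2)
    w_o <- pvec - as.numeric(crossprod(w, pvec)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo > .Machine$double.eps^0.5) {
      w_o <- w_o / nwo
      t_o <- X %*% w_o
      p_o <- crossprod(X, t_o) / sum(t_o^2)
      X <- X - t_o %*% t(p_o)
    }
  }
  fit <- .nipals_pls1(X, y, n_components)
  vip2 <- ncol(X) * as.vector(fit$W^2 %*% fit$ssy) / sum(fit$ssy)
  stats::setNames(sqrt(vip2), colnames(X))
}

#' Apply the three-way significance rule
#'
#' A feature is significant iff p < `p_max` AND (FC > `fc_up` OR
#' FC < `fc_down`) AND VIP > `vip_min` — all three conditions, with no
#' multiple-testing correction by default. Direction follows the fold
#' change. A volcano table (log2 FC, -log10 p) is included. Setting
#' `fdr = TRUE` replaces the raw p-values by Benjamini-Hochberg adjusted
#' ones before thresholding.
#'
#' @param uni Data frame from [univariate_stats()].
#' @param vip Named VIP vector from [plsda_vip()].
#' @param p_max,fc_up,fc_down,vip_min Thresholds (defaults 0.1, 2, 0.5, 1).
#' @param fdr Apply Benjamini-Hochberg correction first (default FALSE).
#' @return `SelectionResult` data frame: `feature_id`, `fold_change`,
#'   `p_value`, `vip`, `significant`, `direction`, `log2_fc`, `neglog10_p`.
#' @export
select_significant <- function(uni, vip, p_max = 0.1, fc_up = 2, fc_down = 0.5,
                               vip_min = 1, fdr = FALSE) {
  v <- vip[uni$feature_id]
  p <- if (fdr) stats::p.adjust(uni$p_value, method = "BH") else uni$p_value
  fc <- uni$fold_change
  sig <- !is.na(p) & p < p_max &
    !is.na(fc) & (fc > fc_up | fc < fc_down) &
    !is.na(v) & v > vip_min
  data.frame(
    feature_id = uni$feature_id, fold_change = fc, p_value = p, vip = unname(v),
    significant = sig,
    direction = ifelse(is.na(fc) | fc == 1, NA_character_,
                       ifelse(fc > 1, "up_in_PD", "up_in_Ctrl")),
    log2_fc = log2(fc), neglog10_p = -log10(p),
    row.names = NULL, stringsAsFactors = FALSE)
}
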