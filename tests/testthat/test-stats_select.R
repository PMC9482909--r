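# IQR filtering, normalization/scaling, univariate statistics, PLS-DA VIP
# and the three-way selection rule.

toy_design <- function(n_pd = 10, n_ctrl = 10) {
  cohort_design(c(sprintf("PD%02d", seq_len(n_pd)),
                  sprintf("CTRL%02d", seq_len(n_ctrl))),
                rep(c("PD", "Ctrl"), c(n_pd, n_ctrl)))
}

toy_matrix <- function(n_feat, design, seed = 1, sdlog = 0.2) {
  set.seed(seed)
  matrix(rlnorm(n_feat * length(design), log(1e5), sdlog),
         n_feat, length(design),
         dimnames = list(sprintf("F%04d", seq_len(n_feat)), names(design)))
}

test_that("the IQR filter follows the size ladder deterministically", {
  des <- toy_design(5, 5)
  m100 <- toy_matrix(100, des)
  expect_equal(nrow(iqr_filter(m100)$matrix), 100)     # < 250: nothing dropped
  m1000 <- matrix(rep(c(1, 2), 5000), 1000, 10,
                  dimnames = list(sprintf("F%04d", 1:1000), names(des)))
  out <- iqr_filter(m1000)                             # < 2000: 25% dropped
  expect_equal(length(out$dropped), 250)
  expect_equal(out$dropped, sort(rownames(m1000))[1:250])  # ties by id
  m <- toy_matrix(300, des)
  m["F0007", ] <- 42                                   # constant: IQR 0
  expect_true("F0007" %in% iqr_filter(m)$dropped)
  expect_error(iqr_filter(m[1:5, ]), "at least 10")
})

test_that("sum normalization equalizes totals and is idempotent", {
  des <- toy_design(3, 3)
  m <- toy_matrix(50, des, seed = 2)
  ns <- normalize_and_scale(m)
  totals <- colSums(ns$normalized)
  expect_equal(unname(totals), rep(mean(colSums(m)), 6), tolerance = 1e-9)
  twice <- normalize_and_scale(ns$normalized)
  expect_equal(twice$normalized, ns$normalized, tolerance = 1e-12)
  bad <- m; bad[, 2] <- 0
  expect_error(normalize_and_scale(bad), colnames(m)[2])
})

test_that("Pareto scaling leaves variance equal to the feature's sd", {
  des <- toy_design(5, 5)
  m <- toy_matrix(40, des, seed = 3)
  ns <- normalize_and_scale(m)
  sds <- apply(ns$normalized, 1, sd)
  expect_equal(unname(apply(ns$scaled, 1, var)), unname(sds), tolerance = 1e-9)
  expect_equal(unname(rowMeans(ns$scaled)), rep(0, 40), tolerance = 1e-12)
  # equal column totals keep a constant row constant after normalization,
  # and the sd-0 guard scales it to zeros
  m2 <- rbind(F1 = c(1, 2, 3), F2 = c(5, 4, 3), F3 = c(7, 7, 7))
  colnames(m2) <- c("PD01", "PD02", "CTRL01")
  ns2 <- normalize_and_scale(m2)
  expect_true(all(ns2$scaled["F3", ] == 0))
})

test_that("fold change and Welch p behave on constructed groups", {
  des <- toy_design(3, 3)
  m <- rbind(F1 = c(20, 20, 20, 10, 10, 10),
             F2 = c(5, 6, 7, 5, 6, 7),
             F3 = rep(100, 6), F4 = rep(100, 6), F5 = rep(100, 6),
             F6 = rep(100, 6), F7 = rep(100, 6), F8 = rep(100, 6),
             F9 = rep(100, 6), F10 = rep(100, 6))
  colnames(m) <- names(des)
  uni <- univariate_stats(m, m - rowMeans(m), des)
  expect_equal(uni$fold_change[1], 2.0, tolerance = 1e-12)
  expect_equal(uni$fold_change[2], 1.0, tolerance = 1e-12)
  expect_gt(uni$p_value[2], 0.9)
  expect_lt(uni$p_value[1], 0.01)
  expect_error(univariate_stats(m[, 1:4], m[, 1:4], des[1:4]), ">= 3 samples")
  mz <- m; mz[1, 4:6] <- 0
  expect_warning(univariate_stats(mz, mz, des), "zero denominator")
})

test_that("VIP scores satisfy sum(VIP^2) = p on every fit", {
  for (seed in 1:5) {
    des <- toy_design(8, 8)
    m <- toy_matrix(60, des, seed = seed)
    m[1:5, seq_len(8)] <- m[1:5, seq_len(8)] * runif(1, 1.5, 4)
    ns <- normalize_and_scale(m)
    for (ortho in c(TRUE, FALSE)) {
      vip <- plsda_vip(ns$scaled, des, orthogonal = ortho)
      expect_equal(sum(vip^2), nrow(m), tolerance = 1e-8)
    }
  }
})

test_that("a single informative feature attains the maximum VIP", {
  set.seed(811)
  des <- toy_design(10, 10)
  m <- toy_matrix(80, des, seed = 812, sdlog = 0.2)
  pd_cols <- names(des)[des == "PD"]
  m["F0042", pd_cols] <- m["F0042", pd_cols] * 8
  ns <- normalize_and_scale(m)
  vip <- plsda_vip(ns$scaled, des)
  expect_identical(names(which.max(vip)), "F0042")
  expect_gt(vip["F0042"], 1)
})

test_that("VIPs on permuted class labels concentrate near 1", {
  set.seed(821)
  des <- toy_design(10, 10)
  m <- toy_matrix(50, des, seed = 822)
  ns <- normalize_and_scale(m)
  vips <- sapply(1:10, function(i) {
    perm <- stats::setNames(sample(unname(des)), names(des))
    plsda_vip(ns$scaled, perm)
  })
  expect_equal(mean(rowMeans(vips^2)), 1, tolerance = 1e-8)
  expect_lt(max(rowMeans(vips)), 1.5)   # no feature systematically important
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  des <- toy_design(8, 8)
  m <- toy_matrix(40, des, seed = 831)
  m[1:4, 1:8] <- m[1:4, 1:8] * 3
  ns <- normalize_and_scale(m)
  mine <- plsda_vip(ns$scaled, des, orthogonal = FALSE, n_components = 1)
  X <- t(ns$scaled)
  fit <- mixOmics::plsda(X, factor(unname(des)), ncomp = 1, scale = FALSE)
  theirs <- mixOmics::vip(fit)[, 1]
  expect_gt(cor(mine[rownames(ns$scaled)], theirs[rownames(ns$scaled)]), 0.999)
})

test_that("the selection rule is the exact three-way conjunction", {
  vip <- c(F1 = 1.5, F2 = 0.5)
  grid <- expand.grid(p = c(0.05, 0.2), fc = c(3, 1.2, 0.3), v = c(1.5, 0.78))
  for (i in seq_len(nrow(grid))) {
    uni <- data.frame(feature_id = "F1", fold_change = grid$fc[i],
                      p_value = grid$p[i])
    sel <- select_significant(uni, c(F1 = grid$v[i]))
    expect_identical(sel$significant,
                     grid$p[i] < 0.1 && (grid$fc[i] > 2 || grid$fc[i] < 0.5) &&
                       grid$v[i] > 1)
  }
  # the VIP = 0.78 exclusion: passes p and FC, fails the VIP gate
  uni <- data.frame(feature_id = "F1", fold_change = 3, p_value = 0.0165)
  expect_false(select_significant(uni, c(F1 = 0.7783))$significant)
  expect_true(select_significant(uni, c(F1 = 2.2821))$significant)
  sel <- select_significant(
    data.frame(feature_id = c("F1", "F2"), fold_change = c(3, 0.23),
               p_value = c(0.05, 0.05)), c(F1 = 1.5, F2 = 1.6))
  expect_identical(sel$direction, c("up_in_PD", "up_in_Ctrl"))
  expect_equal(sel$log2_fc, log2(c(3, 0.23)))
})

test_that("optional FDR correction only weakens the selection", {
  set.seed(841)
  des <- toy_design(5, 5)
  m <- toy_matrix(120, des, seed = 842)
  m[1:6, 1:5] <- m[1:6, 1:5] * 5
  ns <- normalize_and_scale(m)
  uni <- univariate_stats(ns$normalized, ns$scaled, des)
  vip <- plsda_vip(ns$scaled, des)
  raw <- select_significant(uni, vip)
  adj <- select_significant(uni, vip, fdr = TRUE)
  expect_true(all(adj$p_value >= raw$p_value))
  expect_true(all(adj$feature_id[adj$significant] %in%
                    raw$feature_id[raw$significant]))
})
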