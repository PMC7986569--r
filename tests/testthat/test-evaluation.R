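test_that("confusion counts partition the sample and rates follow", {
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  ct <- confusion(truth, truth)
  expect_identical(ct$accuracy, 1)
  expect_identical(ct$tp + ct$fp + ct$tn + ct$fn, ct$total)

  # TP = 40, FN = 10 -> sensitivity 0.80
  calls <- c(rep(1, 40), rep(0, 10))
  ct2 <- confusion(calls, rep(1, 50))
  expect_identical(ct2$sensitivity, 0.8)
  expect_true(is.na(ct2$specificity))  # no negatives in truth

  # all-positive calls on all-negative truth
  ct3 <- confusion(rep(1, 20), rep(0, 20))
  expect_identical(ct3$specificity, 0)
  expect_true(is.na(ct3$sensitivity))
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  # worked example: pos {0.9, 0.4}, neg {0.5, 0.1} -> 3/4 pairs won
  rc <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(rc$auc, 0.75, tolerance = 1e-12)

  expect_equal(roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")

  set.seed(61)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    truth <- c(rep(1, 5), rep(0, 5), rbinom(n - 10, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 6), 1))  # sometimes tied
    expect_equal(roc_curve(scores, truth)$auc,
                 mann_whitney_auc(scores, truth), tolerance = 1e-9)
  }
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(71)
  rc <- roc_curve(runif(50), rbinom(50, 1, 0.5))
  pts <- rc$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$sensitivity[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$sensitivity[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$sensitivity) >= 0))
})

test_that("kappa matches the hand-computed table and its invariances", {
  # contingency a=40 (1,1), b=5 (1,0), c=5 (0,1), d=50 (0,0)
  a <- c(rep(1, 40), rep(1, 5), rep(0, 5), rep(0, 50))
  b <- c(rep(1, 40), rep(0, 5), rep(1, 5), rep(0, 50))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.90, tolerance = 1e-12)
  expect_equal(k$p_e, 0.505, tolerance = 1e-12)
  expect_equal(k$kappa, (0.90 - 0.505) / (1 - 0.505), tolerance = 1e-12)

  # symmetric in raters; invariant to consistent relabeling
  expect_equal(cohens_kappa(b, a)$kappa, k$kappa)
  expect_equal(cohens_kappa(1 - a, 1 - b)$kappa, k$kappa)

  # identical raters with both classes present
  expect_identical(cohens_kappa(a, a)$kappa, 1)
  # both raters constant and equal: p_e = 1, kappa defined as 1
  expect_identical(cohens_kappa(rep(1, 5), rep(1, 5))$kappa, 1)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(81)
  for (rep in 1:20) {
    a <- rbinom(60, 1, 0.4); b <- rbinom(60, 1, 0.6)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
    expect_equal(cohens_kappa(a, b)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-9)
  }
})

test_that("independent raters at matched marginals give kappa near 0", {
  set.seed(91)
  n <- 20000
  a <- rbinom(n, 1, 0.3); b <- rbinom(n, 1, 0.3)
  k <- cohens_kappa(a, b)$kappa
  # kappa of independent raters converges to 0; SE is O(1/sqrt(n))
  expect_lt(abs(k), 4 / sqrt(n))
})

test_that("paired Wilcoxon follows the exact signed-rank distribution", {
  # identical vectors -> p = 1 by convention
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_identical(paired_wilcoxon(x, x)$p.value, 1)

  # n = 6, all differences positive: exact two-sided p = 2/64
  a <- 1:6 + 0.5; b <- rep(0.5, 6)
  res <- paired_wilcoxon(a, b)
  expect_true(res$exact)
  expect_equal(res$p.value, 2 / 64, tolerance = 1e-12)

  # swapping the inputs leaves the two-sided p unchanged
  set.seed(31)
  u <- runif(12); v <- runif(12)
  expect_equal(paired_wilcoxon(u, v)$p.value,
               paired_wilcoxon(v, u)$p.value, tolerance = 1e-12)
})

test_that("exact Wilcoxon matches full sign enumeration for n <= 10", {
  set.seed(41)
  for (n in 3:10) {
    a <- runif(n); b <- runif(n)
    res <- paired_wilcoxon(a, b)
    expect_true(res$exact)
    expect_equal(res$p.value, enum_wilcoxon_p(a - b), tolerance = 1e-9)
  }
})

test_that("large or tied samples fall back to the corrected approximation", {
  set.seed(51)
  a <- runif(40); b <- runif(40)
  res <- paired_wilcoxon(a, b)
  expect_false(res$exact)
  want <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                       correct = TRUE))$p.value
  expect_equal(res$p.value, want, tolerance = 1e-12)

  tied <- paired_wilcoxon(c(1, 2, 3, 4), c(0, 1, 2, 5))  # |d| all 1
  expect_false(tied$exact)
  expect_true(tied$p.value >= 0 && tied$p.value <= 1)
})

test_that("bootstrap CI is seeded and brackets the mean for symmetric data", {
  vals <- c(0.92, 0.95, 0.97, 0.99, 0.94, 0.96)
  ci1 <- bootstrap_ci(vals, seed = 3, n_boot = 2000)
  ci2 <- bootstrap_ci(vals, seed = 3, n_boot = 2000)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, mean(vals))
  expect_gt(ci1$upper, mean(vals))
})
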