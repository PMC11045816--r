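# exact two-sided rank-sum p by full enumeration of group assignments
enumWilcoxP <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  ew <- nx * (n - nx) / 2
  mean(abs(ws - ew) >= abs(wobs - ew) - 1e-12)
}

test_that("rank-sum p-values match full enumeration for small tie-free samples", {
  res <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-4)
  expect_equal(res$p_value, enumWilcoxP(c(1, 2), c(3, 4)), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:5, 1))
    expect_equal(wilcoxonRankSum(x, y)$p_value, enumWilcoxP(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(wilcoxonRankSum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("rank-sum detects a large shift and agrees with a permutation oracle", {
  set.seed(12)
  x <- rnorm(50); y <- rnorm(50, 2)
  res <- wilcoxonRankSum(x, y)
  expect_lt(res$p_value, 1e-6)

  x2 <- rnorm(12); y2 <- rnorm(12, 1)
  p_impl <- wilcoxonRankSum(x2, y2, exactMaxN = 30)$p_value
  r <- rank(c(x2, y2)); n <- 24
  ew <- 12 * 12 / 2
  wobs <- sum(r[1:12]) - 78
  perm <- replicate(1e5, sum(r[sample.int(n, 12)]) - 78)
  p_perm <- mean(abs(perm - ew) >= abs(wobs - ew) - 1e-12)
  expect_equal(p_impl, p_perm, tolerance = 0.01)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(15); y <- rnorm(10, 0.5)
  f <- function(v) exp(v) + v^3
  expect_equal(wilcoxonRankSum(x, y)$p_value,
               wilcoxonRankSum(f(x), f(y))$p_value)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskalWallis(g)$p_value,
               kruskalWallis(lapply(g, f))$p_value)
})

test_that("Kruskal-Wallis handles degenerate groups and matches a permutation oracle", {
  expect_error(kruskalWallis(list(1:3, 4:6)), "3 groups")
  res0 <- kruskalWallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # closed-form H (no ties): 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskalWallis(g)
  r <- rank(unlist(g))
  rb <- tapply(r, rep(1:3, each = 2), mean)
  hOracle <- 12 / (6 * 7) * sum(2 * (rb - mean(r))^2)
  expect_equal(res$statistic, hOracle, tolerance = 1e-12)

  # at moderate n the chi-squared p agrees with a permutation oracle
  set.seed(14)
  g2 <- list(rnorm(12), rnorm(12, 0.8), rnorm(12, 0.3))
  res2 <- kruskalWallis(g2)
  vals <- unlist(g2)
  hStat <- function(v) {
    rr <- rank(v); rbb <- tapply(rr, rep(1:3, each = 12), mean)
    12 / (36 * 37) * sum(12 * (rbb - mean(rr))^2)
  }
  perm <- replicate(2e4, hStat(sample(vals)))
  p_perm <- mean(perm >= res2$statistic - 1e-12)
  expect_equal(res2$p_value, p_perm, tolerance = 0.02)
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(15)
  rej <- mean(replicate(1000, {
    kruskalWallis(split(rnorm(40), rep(1:4, 10)))$p_value < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("BH adjustment follows the step-up formula and its dominance properties", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(16)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p & q <= 1))
  o <- sample(50)
  expect_equal(bhAdjust(p[o]), q[o])  # order equivariance
})

test_that("correlation wraps both methods with a rank-transform oracle for spearman", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlate(x, x^3, "spearman")$r, 1)
  set.seed(17)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(correlate(a, b, "spearman")$r,
               correlate(rank(a), rank(b), "pearson")$r, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), rnorm(5)), "variance")
})

test_that("AUC equals the concordant-pair fraction and the trapezoidal curve area", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  set.seed(18)
  scores <- c(rnorm(20, 1), rnorm(20))
  labels <- rep(c(1, 0), each = 20)
  res <- rocAuc(scores, labels)
  pairs_mat <- outer(scores[labels == 1], scores[labels == 0], "-")
  auc_pairs <- mean((pairs_mat > 0) + 0.5 * (pairs_mat == 0))
  expect_equal(res$auc, auc_pairs, tolerance = 1e-12)
  # trapezoidal area under the sweep curve
  trap <- sum(diff(res$fpr) * (head(res$tpr, -1) + tail(res$tpr, -1)) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-10)
  expect_true(all(diff(res$tpr) >= 0) && all(diff(res$fpr) >= 0))
  # complement property for tie-free scores
  expect_equal(rocAuc(-scores, labels)$auc, 1 - res$auc, tolerance = 1e-12)
  expect_error(rocAuc(scores, rep(1, 40)), "both classes")
})

test_that("AUC matches the pROC reference on random data", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:5) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(rocAuc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("confusion matrix counts and accuracy behave", {
  cm <- confusionAccuracy(c(1, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(sum(cm$matrix), 4)
  expect_equal(confusionAccuracy(c(1, 0), c(1, 0))$accuracy, 1)
  expect_equal(confusionAccuracy(c(1, 0), c(0, 1))$accuracy, 0)
  expect_error(confusionAccuracy(1, c(1, 0)), "mismatch")
})

test_that("Hosmer-Lemeshow is calibrated on well-specified probabilities and rejects miscalibration", {
  set.seed(20)
  pvals <- replicate(100, {
    prob <- runif(1e4, 0.05, 0.95)
    hosmerLemeshow(prob, rbinom(1e4, 1, prob), fitted = FALSE)$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.9)

  prob <- runif(5000, 0.05, 0.95)
  truth <- rbinom(5000, 1, prob)
  expect_lt(hosmerLemeshow(prob^2, truth, fitted = FALSE)$p_value, 0.01)

  # identical probabilities collapse to one bin; exact balance gives chi2 0
  res <- suppressWarnings(
    hosmerLemeshow(rep(0.5, 10), rep(c(0, 1), 5)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(hosmerLemeshow(runif(10), rbinom(10, 1, 0.5), g = 2), ">= 3")
})

test_that("significance stars map p-value ranges as reported", {
  expect_equal(significanceStars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
})
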