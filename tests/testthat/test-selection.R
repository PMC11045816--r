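plantedXY <- function(seed, n = 200, pNoise = 30, d = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * (pNoise + 2)), n, pNoise + 2)
  colnames(X) <- c("hit1", "hit2", paste0("noise", seq_len(pNoise)))
  y <- rep(0:1, each = n / 2)
  X[, "hit1"] <- X[, "hit1"] + d * y
  X[, "hit2"] <- X[, "hit2"] - d * y
  list(X = X, y = y)
}

test_that("Boruta confirms planted features, rejects noise, and never returns shadows", {
  ok <- vapply(1:10, function(s) {
    d <- plantedXY(700 + s)
    b <- borutaSelect(d$X, d$y, seed = s)
    all(c("hit1", "hit2") %in% b$selected) &&
      mean(!paste0("noise", 1:30) %in% b$selected) >= 0.9 &&
      !any(grepl("shadow", b$selected))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(borutaSelect(matrix(rnorm(40), 10, 4), rep(0:1, 5)),
               "20 samples")
  expect_error(borutaSelect(plantedXY(1)$X, plantedXY(1)$y, maxIter = 5),
               "maxIter")
})

test_that("Boruta confirms nothing on pure noise", {
  nconf <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 20), 60, 20)
    length(borutaSelect(X, rep(0:1, 30), seed = s)$selected)
  }, integer(1))
  expect_gte(mean(nconf == 0), 0.9)
})

test_that("lasso shrinks everything at infinite penalty and finds a predictive feature", {
  d <- plantedXY(71, n = 100, pNoise = 10, d = 3)
  res_inf <- lassoSelect(d$X, d$y, lambda = 1e6)
  expect_length(res_inf$selected, 0L)

  res <- lassoSelect(d$X, d$y, seed = 1)
  expect_true(all(c("hit1", "hit2") %in% res$selected))
  expect_gt(res$importance[["hit1"]], 0)
  expect_lt(res$importance[["hit2"]], 0)
  expect_lte(length(res$selected), ncol(d$X))

  # duplicated columns cannot inflate the selection beyond the input
  Xd <- cbind(d$X, dup = d$X[, "hit1"])
  resd <- lassoSelect(Xd, d$y, seed = 1)
  expect_lte(length(resd$selected), ncol(Xd))
})

test_that("SVM-RFE keeps informative features in the minimal-error subset", {
  ok <- vapply(1:10, function(s) {
    d <- plantedXY(720 + s, n = 300, pNoise = 8, d = 3)
    r <- svmRfeSelect(d$X, d$y, seed = s)
    all(c("hit1", "hit2") %in% r$selected) && length(r$selected) <= 4
  }, logical(1))
  expect_gte(mean(ok), 0.8)

  d <- plantedXY(73, n = 100, pNoise = 8)
  r <- svmRfeSelect(d$X, d$y, seed = 1)
  expect_length(r$cvError, ncol(d$X))   # one value per subset size

  # all-noise: CV error stays near the majority-class rate at every size
  set.seed(74)
  Xn <- matrix(rnorm(120 * 6), 120, 6); yn <- rep(0:1, 60)
  rn <- svmRfeSelect(Xn, yn, seed = 2)
  expect_true(all(abs(rn$cvError - 0.5) < 0.2))
  expect_error(svmRfeSelect(d$X, rep(1, 100)), "binary")
})

test_that("random-forest Gini ranking puts separating features first", {
  set.seed(75)
  X <- matrix(rnorm(100 * 6), 100, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(0:1, each = 50)
  X[, "f3"] <- y * 4 + rnorm(100, 0, 0.01)   # perfect splitter
  r <- rfGiniRank(X, y, seed = 1)
  expect_equal(names(sort(r$importance, decreasing = TRUE))[1], "f3")
  expect_true(all(r$importance >= 0 & is.finite(r$importance)))
  expect_error(rfGiniRank(X, y, nTrees = 100), "200")

  ok <- vapply(1:10, function(s) {
    d <- plantedXY(750 + s, n = 150, pNoise = 10)
    imp <- rfGiniRank(d$X, d$y, seed = s)$importance
    all(rank(-imp)[c("hit1", "hit2")] <= 2)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("boosting gain is zero for unused features and ranks planted ones on top", {
  set.seed(76)
  X <- matrix(rnorm(100 * 5), 100, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- as.integer(X[, 1] > 0)
  r <- gbmRank(X, y, seed = 1)
  expect_equal(sum(r$importance), 1, tolerance = 1e-6)  # gains normalized
  expect_equal(names(which.max(r$importance)), "f1")
  expect_error(gbmRank(X, y, nRounds = 10), "50")

  ok <- vapply(1:10, function(s) {
    d <- plantedXY(760 + s, n = 150, pNoise = 10)
    imp <- gbmRank(d$X, d$y, seed = s)$importance
    all(rank(-imp)[c("hit1", "hit2")] <= 2)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("hub intersection is the five-way set intersection with a membership matrix", {
  mk <- function(sel) list(method = paste0("m", length(sel)), selected = sel)
  res <- list(mk(c("A", "B", "C")), mk(c("B", "C")), mk(c("B", "C", "D")),
              mk(c("B", "C")), mk(c("B", "C", "E")))
  ih <- intersectHubs(res)
  expect_setequal(ih$hubs, c("B", "C"))
  expect_equal(dim(ih$membership), c(5L, 5L))
  # order invariance and idempotence
  ih2 <- intersectHubs(res[c(3, 1, 5, 2, 4)])
  expect_setequal(ih2$hubs, ih$hubs)
  same <- replicate(5, mk(c("X", "Y")), simplify = FALSE)
  expect_setequal(intersectHubs(same)$hubs, c("X", "Y"))
  expect_error(intersectHubs(res[1:3]), "exactly 5")
  res[[2]]$selected <- character()
  expect_warning(intersectHubs(res), "empty")
})

test_that("label permutation empties the hub intersection", {
  d <- plantedXY(77, n = 120, pNoise = 14)
  set.seed(78)
  nhubs <- vapply(1:10, function(i) {
    yp <- sample(d$y)
    res <- list(borutaSelect(d$X, yp, maxIter = 20 + 5, seed = i),
                lassoSelect(d$X, yp, seed = i),
                svmRfeSelect(d$X, yp, seed = i),
                rfGiniRank(d$X, yp, topN = 3, seed = i),
                gbmRank(d$X, yp, topN = 3, seed = i))
    length(suppressWarnings(intersectHubs(res))$hubs)
  }, integer(1))
  expect_lte(mean(nhubs), 0.5)
})

test_that("selectors are deterministic given data and seed", {
  d <- plantedXY(79, n = 100, pNoise = 6)
  expect_identical(lassoSelect(d$X, d$y, seed = 3)$selected,
                   lassoSelect(d$X, d$y, seed = 3)$selected)
  expect_identical(borutaSelect(d$X, d$y, seed = 3)$selected,
                   borutaSelect(d$X, d$y, seed = 3)$selected)
  expect_identical(gbmRank(d$X, d$y, seed = 3)$importance,
                   gbmRank(d$X, d$y, seed = 3)$importance)
})
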