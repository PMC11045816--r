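encFixture <- function(seed = 81, n = 120) {
  set.seed(seed)
  # four genes: three shifted up in UC, one down
  grp <- rep(c("UC", "HC"), c(n * 0.8, n * 0.2))
  v <- rbind(gA = rnorm(n) + 1.5 * (grp == "UC"),
             gB = rnorm(n) + 1.5 * (grp == "UC"),
             gC = rnorm(n) + 1.5 * (grp == "UC"),
             gD = rnorm(n) - 1.5 * (grp == "UC")) + 7
  colnames(v) <- paste0("s", seq_len(n))
  UCExperiment(v, data.frame(group = grp))
}

test_that("gene-score encoding applies the median threshold rule per direction", {
  v <- rbind(up = c(5, 3, 4, 4.5), down = c(3, 5, 4, 3.5)) + 0
  colnames(v) <- paste0("s", 1:4)
  ue <- UCExperiment(v, data.frame(group = c("UC", "UC", "HC", "HC")))
  enc <- encodeGeneScores(ue, c("up", "down"),
                          directions = c("up_in_UC", "down_in_UC"),
                          medians = c(4, 4))
  expect_equal(enc$scores[, "up"], c(s1 = 1, s2 = 0, s3 = 0, s4 = 1))
  expect_equal(enc$scores[, "down"], c(s1 = 1, s2 = 0, s3 = 0, s4 = 1))
  expect_true(all(enc$scores %in% 0:1))
  expect_error(encodeGeneScores(ue, "missing"), "missing")
})

test_that("encoding is invariant to strictly monotone transforms and infers directions", {
  ue <- encFixture()
  enc1 <- encodeGeneScores(ue, c("gA", "gD"))
  expect_equal(unname(enc1$directions), c("up_in_UC", "down_in_UC"))
  v2 <- exp(exprValues(ue) / 4)
  ue2 <- UCExperiment(v2, sampleMeta(ue))
  enc2 <- encodeGeneScores(ue2, c("gA", "gD"))
  expect_equal(enc1$scores, enc2$scores)
})

test_that("the network fits separable encodings perfectly and retrains identically", {
  set.seed(82)
  n <- 60
  scores <- cbind(g1 = rep(0:1, each = n / 2), g2 = rbinom(n, 1, 0.5))
  rownames(scores) <- paste0("s", seq_len(n))
  labels <- scores[, "g1"]
  enc <- list(scores = scores, medians = c(g1 = 0.5, g2 = 0.5),
              directions = c(g1 = "up_in_UC", g2 = "up_in_UC"))
  m <- trainAnn(enc, labels, seed = 1)
  pred <- as.integer(neuralScore(m, scores) >= 0.5)
  expect_equal(mean(pred == labels), 1)

  m2 <- trainAnn(enc, labels, seed = 1)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@W2, m2@W2)
  expect_error(trainAnn(enc, labels + 1, seed = 1), "binary")
})

test_that("with labels independent of scores the holdout AUC stays near chance", {
  set.seed(83)
  aucs <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 160
    scores <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                     dimnames = list(paste0("s", 1:n), paste0("g", 1:4)))
    labels <- rbinom(n, 1, 0.5)
    sp <- splitStratified(labels, 0.7, seed = s)
    enc <- list(scores = scores[sp$train, ],
                medians = setNames(rep(0.5, 4), paste0("g", 1:4)),
                directions = setNames(rep("up_in_UC", 4), paste0("g", 1:4)))
    m <- trainAnn(enc, labels[sp$train], seed = s)
    rocAuc(neuralScore(m, scores[sp$test, ]), labels[sp$test])$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the forward pass matches closed forms and is vectorization-consistent", {
  m <- new("DiagnosticModel", genes = c("a", "b"),
           medians = c(a = 0, b = 0),
           directions = c(a = "up_in_UC", b = "up_in_UC"),
           W1 = matrix(0, 3, 3), W2 = matrix(c(0.7, 0, 0, 0), 1, 4),
           threshold = 0.5)
  sc <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2,
               dimnames = list(paste0("s", 1:4), c("a", "b")))
  p <- neuralScore(m, sc)
  expect_equal(unname(p), rep(1 / (1 + exp(-0.7)), 4))  # logistic(bias)

  # positive-weight network is monotone in an up-gene score
  mp <- new("DiagnosticModel", genes = c("a", "b"),
            medians = c(a = 0, b = 0),
            directions = c(a = "up_in_UC", b = "up_in_UC"),
            W1 = matrix(abs(rnorm(9)), 3, 3),
            W2 = matrix(abs(rnorm(4)), 1, 4), threshold = 0.5)
  p00 <- neuralScore(mp, matrix(c(0, 0), 1, 2,
                                dimnames = list("s", c("a", "b"))))
  p10 <- neuralScore(mp, matrix(c(1, 0), 1, 2,
                                dimnames = list("s", c("a", "b"))))
  expect_gte(p10, p00)

  loopP <- vapply(seq_len(nrow(sc)), function(i)
    neuralScore(m, sc[i, , drop = FALSE]), numeric(1))
  expect_equal(unname(p), unname(loopP))
  expect_error(neuralScore(m, sc[, 1, drop = FALSE]), "expects")
})

test_that("the trained network reproduces the reference optimizer's predictions", {
  ue <- encFixture(seed = 84, n = 200)
  labels <- as.integer(sampleMeta(ue)$group == "UC")
  enc <- encodeGeneScores(ue, c("gA", "gB", "gC", "gD"))
  set.seed(5)
  ref <- nnet::nnet(x = enc$scores, y = labels, size = 5, entropy = TRUE,
                    maxit = 2000, abstol = 1e-6, reltol = 1e-6, decay = 0,
                    trace = FALSE)
  m <- trainAnn(enc, labels, seed = 5)
  expect_equal(unname(neuralScore(m, enc$scores)),
               unname(drop(predict(ref, enc$scores))), tolerance = 1e-10)
})

test_that("diagnostic evaluation reports ROC, confusion and calibration on a holdout", {
  ue <- encFixture(seed = 85, n = 300)
  labels <- as.integer(sampleMeta(ue)$group == "UC")
  sp <- splitStratified(labels, 0.7, seed = 1)
  enc <- encodeGeneScores(ue[, sp$train], c("gA", "gB", "gC", "gD"))
  m <- trainAnn(enc, labels[sp$train], seed = 1)
  ev <- evaluateDiagnostic(m, ue[, sp$test])
  expect_gt(ev$roc$auc, 0.8)
  expect_equal(sum(ev$confusion), length(sp$test))
  expect_true(ev$hl$p_value >= 0 && ev$hl$p_value <= 1)

  # threshold 1 predicts everything negative
  m@threshold <- 1 + 1e-9
  ev1 <- evaluateDiagnostic(m, ue[, sp$test])
  expect_equal(ev1$accuracy, mean(labels[sp$test] == 0))
  expect_error(evaluateDiagnostic(m, ue[, which(labels == 1)[1:20]]),
               "both classes")
})

test_that("model JSON serialization round-trips weights and encoding exactly", {
  ue <- encFixture(seed = 86)
  labels <- as.integer(sampleMeta(ue)$group == "UC")
  enc <- encodeGeneScores(ue, c("gA", "gB"))
  m <- trainAnn(enc, labels, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  writeDiagnosticModel(m, f)
  m2 <- readDiagnosticModel(f)
  expect_equal(m2@W1, m@W1, ignore_attr = TRUE)
  expect_equal(m2@W2, m@W2, ignore_attr = TRUE)
  expect_equal(neuralScore(m2, enc$scores), neuralScore(m, enc$scores))
})
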