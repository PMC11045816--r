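.asBinaryFactor <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2L) stop("labels must be binary")
  f
}

.selectionResult <- function(method, importance, selected, params, seed,
                             extra = list()) {
  c(list(method = method, importance = importance, selected = selected,
         params = params, seed = seed), extra)
}

#' Boruta all-relevant feature selection
#'
#' Wrapper around random-forest importance: each iteration appends a
#' column-shuffled shadow copy of every undecided feature, fits a forest
#' (impurity/Gini importance), and scores a hit when a real feature's
#' importance exceeds the maximum shadow importance. Accumulated hits are
#' tested against Binomial(trials, 0.5) two-sided with BH correction across
#' the undecided features; significantly-above features are confirmed,
#' significantly-below rejected, the rest stay tentative.
#'
#' @param X samples x features numeric matrix (>= 20 samples).
#' @param y binary labels.
#' @param maxIter maximum iterations (>= 20).
#' @param alpha significance level for the binomial decisions.
#' @param nTrees trees per forest.
#' @param seed integer seed.
#' @return Selection result: \code{selected} (confirmed features),
#'   \code{tentative}, \code{importance} (hit fraction), \code{params},
#'   \code{seed}.
#' @export
borutaSelect <- function(X, y, maxIter = 50L, alpha = 0.05, nTrees = 300L,
                         seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 20L) stop("need >= 20 samples")
  y <- .asBinaryFactor(y)
  if (maxIter < 20L) stop("maxIter must be >= 20")
  p <- ncol(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(p))
  status <- stats::setNames(rep("undecided", p), feats)
  hits <- trials <- stats::setNames(integer(p), feats)
  set.seed(seed)
  for (iter in seq_len(maxIter)) {
    und <- names(status)[status == "undecided"]
    if (!length(und)) break
    Xu <- X[, und, drop = FALSE]
    # shadows are fresh shuffles of every original feature: late survivors
    # must still beat the maximum over the full shadow pool, which keeps the
    # null hit rate far below 1/2 as the undecided pool shrinks
    shadow <- apply(X, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", seq_len(p))
    df <- data.frame(cbind(Xu, shadow), check.names = FALSE)
    df$.y <- y
    rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                         num.trees = nTrees, importance = "impurity",
                         num.threads = 1L, seed = seed + iter)
    imp <- rf$variable.importance
    maxShadow <- max(imp[colnames(shadow)])
    hits[und] <- hits[und] + (imp[und] > maxShadow)
    trials[und] <- trials[und] + 1L
    pv <- vapply(und, function(f)
      stats::binom.test(hits[[f]], trials[[f]], 0.5)$p.value, numeric(1))
    pv <- bhAdjust(pv)
    status[und[pv < alpha & hits[und] > trials[und] / 2]] <- "confirmed"
    status[und[pv < alpha & hits[und] < trials[und] / 2]] <- "rejected"
  }
  .selectionResult(
    "boruta", importance = hits / pmax(trials, 1L),
    selected = names(status)[status == "confirmed"],
    params = list(maxIter = maxIter, alpha = alpha, nTrees = nTrees),
    seed = seed,
    extra = list(tentative = names(status)[status == "undecided"],
                 status = status))
}

#' L1-penalized logistic regression selection
#'
#' Columns are standardized, the penalty is chosen by cross-validated
#' binomial deviance (lambda at the minimum), and features with nonzero
#' coefficients are selected.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param nFolds CV folds (default 10).
#' @param seed integer seed.
#' @param lambda optional fixed penalty; skips cross-validation when given.
#' @return Selection result with per-feature coefficients as importance.
#' @export
lassoSelect <- function(X, y, nFolds = 10L, seed = 1L, lambda = NULL) {
  X <- scale(as.matrix(X))
  y <- .asBinaryFactor(y)
  set.seed(seed)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = nFolds,
                            type.measure = "deviance")
    lambda <- cv$lambda.min
    fit <- cv
  } else {
    fit <- glmnet::glmnet(X, y, family = "binomial")
  }
  co <- as.vector(stats::coef(fit, s = lambda))[-1L]
  names(co) <- colnames(X)
  .selectionResult("lasso", importance = co,
                   selected = names(co)[co != 0],
                   params = list(nFolds = nFolds, lambda = lambda),
                   seed = seed)
}

.svmWeights <- function(X, y, cost = 1) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  drop(t(fit$coefs) %*% fit$SV)
}

#' SVM recursive feature elimination
#'
#' Linear-kernel maximum-margin classifier; the feature with the smallest
#' squared weight is eliminated recursively to produce a ranking, and the
#' cross-validated error rate is recorded for every subset size (the top-s
#' ranked features). The selected subset is the size with minimal CV error;
#' ties go to the smaller subset.
#'
#' @param X samples x features matrix (standardized internally).
#' @param y binary labels; each class must have at least \code{nFolds}
#'   samples.
#' @param nFolds CV folds (default 10).
#' @param cost SVM cost parameter.
#' @param seed integer seed.
#' @return Selection result with \code{ranking} (best first) and
#'   \code{cvError} (one value per subset size 1..p).
#' @export
svmRfeSelect <- function(X, y, nFolds = 10L, cost = 1, seed = 1L) {
  X <- scale(as.matrix(X))
  y <- .asBinaryFactor(y)
  if (min(table(y)) < nFolds) stop("each class needs >= nFolds samples")
  p <- ncol(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(p))
  remaining <- feats
  elim <- character(0)
  while (length(remaining) > 1L) {
    w <- .svmWeights(X[, remaining, drop = FALSE], y, cost)
    worst <- remaining[which.min(w^2)]
    elim <- c(worst, elim)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(remaining, elim)   # best first
  set.seed(seed)
  folds <- sample(rep_len(seq_len(nFolds), nrow(X)))
  cvError <- vapply(seq_len(p), function(s) {
    fs <- ranking[seq_len(s)]
    errs <- vapply(seq_len(nFolds), function(f) {
      tr <- folds != f
      fit <- e1071::svm(X[tr, fs, drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      mean(stats::predict(fit, X[!tr, fs, drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  sBest <- which.min(cvError)
  .selectionResult("svm_rfe",
                   importance = stats::setNames(rev(seq_len(p)),
                                                ranking)[feats],
                   selected = ranking[seq_len(sBest)],
                   params = list(nFolds = nFolds, cost = cost,
                                 bestSize = sBest),
                   seed = seed,
                   extra = list(ranking = ranking, cvError = cvError))
}

#' Random-forest Gini importance ranking
#'
#' Mean decrease in Gini impurity per feature; the top \code{topN} features
#' are selected.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param nTrees number of trees (>= 200).
#' @param topN selection size (default 10).
#' @param seed integer seed.
#' @return Selection result with Gini importances.
#' @export
rfGiniRank <- function(X, y, nTrees = 500L, topN = 10L, seed = 1L) {
  if (nTrees < 200L) stop("nTrees must be >= 200")
  X <- as.matrix(X)
  y <- .asBinaryFactor(y)
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = nTrees)
  imp <- drop(rf$importance[, "MeanDecreaseGini"])
  .selectionResult("rf_gini", importance = imp,
                   selected = names(sort(imp, decreasing = TRUE))[
                     seq_len(min(topN, length(imp)))],
                   params = list(nTrees = nTrees, topN = topN), seed = seed)
}

#' Gradient-boosted trees gain ranking
#'
#' Gradient boosting with logistic loss; per-feature total gain is the
#' importance (features never used gain 0), and the top \code{topN} are
#' selected.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param nRounds boosting rounds (>= 50).
#' @param topN selection size (default 10).
#' @param seed integer seed.
#' @param eta,maxDepth boosting hyperparameters.
#' @return Selection result with gain importances.
#' @export
gbmRank <- function(X, y, nRounds = 100L, topN = 10L, seed = 1L, eta = 0.3,
                    maxDepth = 3L) {
  if (nRounds < 50L) stop("nRounds must be >= 50")
  X <- as.matrix(X)
  ylab <- as.integer(.asBinaryFactor(y)) - 1L
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(X, label = ylab, nthread = 1L)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_depth = maxDepth, nthread = 1L),
    data = dm, nrounds = nRounds, verbose = 0)
  it <- xgboost::xgb.importance(model = bst)
  imp <- stats::setNames(rep(0, length(feats)), feats)
  imp[it$Feature] <- it$Gain
  .selectionResult("gbm", importance = imp,
                   selected = names(sort(imp, decreasing = TRUE))[
                     seq_len(min(topN, length(imp)))],
                   params = list(nRounds = nRounds, topN = topN, eta = eta,
                                 maxDepth = maxDepth),
                   seed = seed)
}

#' Intersect the five selectors' gene sets into hub genes
#'
#' @param results list of exactly 5 selection results (from the five
#'   selectors); an empty selection triggers a warning since it forces an
#'   empty intersection.
#' @return List with \code{hubs} (the intersection) and \code{membership}
#'   (genes x methods logical matrix for Venn plotting).
#' @export
intersectHubs <- function(results) {
  if (length(results) != 5L) stop("exactly 5 selection results required")
  sets <- lapply(results, `[[`, "selected")
  methods <- vapply(results, `[[`, character(1), "method")
  if (any(!lengths(sets)))
    warning("empty selection from: ",
            paste(methods[!lengths(sets)], collapse = ", "))
  hubs <- Reduce(intersect, sets)
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes)) {
    dimnames(membership) <- list(genes, methods)
  }
  list(hubs = hubs, membership = membership)
}
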