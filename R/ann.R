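.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binarize hub-gene expression against cohort medians
#'
#' Per gene, the encoding threshold is the cohort median; a sample scores 1
#' when its expression lies on the gene's disease-typical side of that
#' median (above it for an \code{up_in_UC} gene, below it for
#' \code{down_in_UC}), else 0. The rule is rank-based, hence invariant to
#' monotone transforms of expression. When directions are not supplied they
#' are determined from the cohort's UC-vs-HC rank shift (sign of the mean
#' rank difference).
#'
#' @param ue a \linkS4class{UCExperiment} with >= 3 samples; all
#'   \code{genes} must be present.
#' @param genes hub gene ids.
#' @param directions optional per-gene \code{"up_in_UC"}/\code{"down_in_UC"}.
#' @param medians optional per-gene thresholds (e.g. from a training
#'   cohort); computed from \code{ue} when \code{NULL}.
#' @return List: \code{scores} (samples x genes 0/1 matrix), \code{medians},
#'   \code{directions}.
#' @export
encodeGeneScores <- function(ue, genes, directions = NULL, medians = NULL) {
  v <- exprValues(ue)
  missing_g <- setdiff(genes, rownames(v))
  if (length(missing_g))
    stop("hub gene(s) missing from matrix: ",
         paste(missing_g, collapse = ", "))
  if (ncol(v) < 3L) stop("cohort must have >= 3 samples")
  v <- v[genes, , drop = FALSE]
  if (is.null(medians)) medians <- apply(v, 1L, stats::median)
  if (is.null(directions)) {
    grp <- sampleMeta(ue)$group
    if (!all(c("UC", "HC") %in% grp))
      stop("directions not supplied and cohort lacks both UC and HC samples")
    directions <- apply(v, 1L, function(x) {
      r <- rank(x)
      if (mean(r[grp == "UC"]) >= mean(r[grp == "HC"])) "up_in_UC"
      else "down_in_UC"
    })
  }
  stopifnot(length(medians) == length(genes),
            length(directions) == length(genes),
            all(directions %in% c("up_in_UC", "down_in_UC")))
  scores <- vapply(seq_along(genes), function(i) {
    if (directions[[i]] == "up_in_UC") as.integer(v[i, ] > medians[[i]])
    else as.integer(v[i, ] < medians[[i]])
  }, integer(ncol(v)))
  dimnames(scores) <- list(colnames(v), genes)
  list(scores = scores,
       medians = stats::setNames(as.numeric(medians), genes),
       directions = stats::setNames(as.character(directions), genes))
}

#' Train the binarized-score neural diagnostic
#'
#' Fits a feedforward network with one hidden layer of \code{hidden}
#' logistic units and a single logistic output on the 0/1 gene scores,
#' minimizing cross-entropy until convergence (loss change below \code{tol}
#' or \code{maxEpochs}). Weight initialization is seeded, so retraining with
#' the same data and seed reproduces identical weights.
#'
#' @param encoding result of \code{\link{encodeGeneScores}}.
#' @param labels binary outcome per sample (1 = UC); both classes need >= 10
#'   samples.
#' @param hidden hidden units (default 5).
#' @param seed integer seed.
#' @param maxEpochs optimizer iteration cap.
#' @param tol convergence tolerance on the loss.
#' @param decay optional weight decay (default 0).
#' @param threshold decision threshold on the output probability.
#' @return A \linkS4class{DiagnosticModel}.
#' @export
trainAnn <- function(encoding, labels, hidden = 5L, seed = 1L,
                     maxEpochs = 2000L, tol = 1e-6, decay = 0,
                     threshold = 0.5) {
  X <- encoding$scores
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (min(table(y)) < 10L) stop("both classes need >= 10 samples")
  set.seed(seed)
  fit <- nnet::nnet(x = X, y = y, size = hidden, entropy = TRUE,
                    maxit = maxEpochs, abstol = tol, reltol = tol,
                    decay = decay, trace = FALSE)
  p <- ncol(X)
  # nnet weight layout: per hidden unit (bias, inputs), then output
  # (bias, hidden)
  W1 <- matrix(fit$wts[seq_len(hidden * (p + 1L))], nrow = hidden,
               ncol = p + 1L, byrow = TRUE)
  W2 <- matrix(fit$wts[hidden * (p + 1L) + seq_len(hidden + 1L)], nrow = 1L)
  new("DiagnosticModel", genes = colnames(X), medians = encoding$medians,
      directions = encoding$directions, W1 = W1, W2 = W2,
      threshold = threshold)
}

#' Score samples with the neural diagnostic
#'
#' Forward pass of the trained network over 0/1 gene-score vectors; returns
#' the UC probability in (0, 1) per sample.
#'
#' @param model a \linkS4class{DiagnosticModel}.
#' @param scores samples x genes 0/1 matrix whose columns match
#'   \code{modelGenes(model)} (an encoding list is also accepted).
#' @return Named numeric vector of probabilities.
#' @export
neuralScore <- function(model, scores) {
  if (is.list(scores)) scores <- scores$scores
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model@genes))
    stop("score matrix has ", ncol(scores), " columns; model expects ",
         length(model@genes))
  if (!is.null(colnames(scores)) &&
      !identical(colnames(scores), model@genes))
    scores <- scores[, model@genes, drop = FALSE]
  H <- .sigmoid(model@W1 %*% t(cbind(1, scores)))
  drop(.sigmoid(model@W2 %*% rbind(1, H)))
}

#' Evaluate the diagnostic on a holdout cohort
#'
#' Encodes the holdout with the model's stored medians and directions,
#' scores it, and reports ROC/AUC, the confusion matrix with accuracy at the
#' model's decision threshold, and the Hosmer-Lemeshow calibration test.
#'
#' @param model a \linkS4class{DiagnosticModel}.
#' @param ue holdout \linkS4class{UCExperiment} containing both classes.
#' @param hlBins Hosmer-Lemeshow bins (default 10).
#' @return List: \code{prob}, \code{roc} (see \code{\link{rocAuc}}),
#'   \code{confusion}, \code{accuracy}, \code{hl}.
#' @export
evaluateDiagnostic <- function(model, ue, hlBins = 10L) {
  labels <- as.integer(sampleMeta(ue)$group == "UC")
  if (length(unique(labels)) < 2L) stop("holdout must contain both classes")
  enc <- encodeGeneScores(ue, model@genes, directions = model@directions,
                          medians = model@medians)
  prob <- neuralScore(model, enc$scores)
  roc <- rocAuc(prob, labels)
  cm <- confusionAccuracy(as.integer(prob >= model@threshold), labels)
  prob_hl <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  hl <- suppressWarnings(hosmerLemeshow(prob_hl, labels, g = hlBins))
  list(prob = prob, roc = roc, confusion = cm$matrix,
       accuracy = cm$accuracy, hl = hl)
}

#' Stratified train/holdout split
#'
#' @param labels binary (or factor) vector.
#' @param trainFrac training fraction (default 0.7).
#' @param seed integer seed.
#' @return List of integer index vectors \code{train} and \code{test}.
#' @export
splitStratified <- function(labels, trainFrac = 0.7, seed = 1L) {
  set.seed(seed)
  idx <- split(seq_along(labels), labels)
  train <- sort(unlist(lapply(idx, function(i)
    sample(i, round(trainFrac * length(i))))))
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Serialize / restore a DiagnosticModel as JSON
#'
#' @param model a \linkS4class{DiagnosticModel}.
#' @param path output (input) JSON file.
#' @return \code{writeDiagnosticModel} returns \code{path} invisibly;
#'   \code{readDiagnosticModel} the restored model.
#' @export
writeDiagnosticModel <- function(model, path) {
  obj <- list(genes = model@genes, medians = model@medians,
              directions = model@directions, W1 = model@W1, W2 = model@W2,
              threshold = model@threshold)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDiagnosticModel
#' @export
readDiagnosticModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DiagnosticModel", genes = obj$genes,
      medians = stats::setNames(as.numeric(obj$medians), obj$genes),
      directions = stats::setNames(as.character(obj$directions), obj$genes),
      W1 = matrix(unlist(obj$W1), nrow = nrow(as.matrix(obj$W1))),
      W2 = matrix(unlist(obj$W2), nrow = 1L),
      threshold = obj$threshold)
}
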