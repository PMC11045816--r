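#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups. The p-value is exact (full
#' enumeration of rank assignments) when the combined sample size is at most
#' \code{exactMaxN} and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param exactMaxN combined-n cutoff for the exact null (default 20).
#' @return List with \code{statistic} (W), \code{p_value}, \code{method},
#'   \code{n} (per-group sizes).
#' @export
wilcoxonRankSum <- function(x, y, exactMaxN = 20L) {
  if (!length(x) || !length(y)) stop("both vectors must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "wilcoxon-degenerate", n = c(length(x), length(y))))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exactMaxN
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # zero-variance rank distribution
  list(statistic = unname(ht$statistic), p_value = min(p, 1),
       method = if (exact) "wilcoxon-exact" else "wilcoxon-normal",
       n = c(length(x), length(y)))
}

#' Kruskal-Wallis test across three or more groups
#'
#' @param groups list of at least 3 non-empty numeric vectors.
#' @return List with \code{statistic} (H, tie-corrected), \code{p_value}
#'   (chi-squared, k-1 df), \code{method}, \code{n}.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need >= 3 groups; use wilcoxonRankSum() for two")
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  if (length(unique(unlist(groups))) == 1L)
    return(list(statistic = 0, p_value = 1, method = "kruskal-degenerate",
                n = lengths(groups)))
  ht <- stats::kruskal.test(groups)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "kruskal-wallis", n = lengths(groups))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted values (same order as input), capped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson or Spearman correlation with p-value
#'
#' @param x,y numeric vectors of equal length >= 3 and nonzero variance.
#' @param method \code{"pearson"} (t-distribution p) or \code{"spearman"}.
#' @return List with \code{r}, \code{p_value}, \code{method}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_value = ht$p.value, method = method)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the score vector (predict positive when score >=
#' threshold) plus the rank-statistic AUC, in which tied score pairs are
#' credited 0.5 — identical to the trapezoidal area under the sweep curve.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or 2-level factor); 1 = positive.
#' @return List with \code{thresholds}, \code{tpr}, \code{fpr}, \code{auc}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(as.logical(as.integer(as.factor(labels)) - 1L))
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  ord <- order(scores, decreasing = TRUE)
  tp <- fp <- numeric(length(thr)); tp[1] <- fp[1] <- 0
  cs_pos <- cumsum(labels[ord] == 1L)
  cs_neg <- cumsum(labels[ord] == 0L)
  s_sorted <- scores[ord]
  for (i in seq_along(thr)[-1L]) {
    k <- max(which(s_sorted >= thr[i]))
    tp[i] <- cs_pos[k]; fp[i] <- cs_neg[k]
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(thresholds = thr, tpr = tp / npos, fpr = fp / nneg, auc = auc)
}

#' Confusion matrix and accuracy
#'
#' @param pred,truth binary vectors of equal length.
#' @return List with \code{matrix} (2x2: truth in rows, prediction in
#'   columns) and \code{accuracy}.
#' @export
confusionAccuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  pred <- factor(as.integer(pred), levels = c(0, 1))
  truth <- factor(as.integer(truth), levels = c(0, 1))
  m <- table(truth = truth, predicted = pred)
  list(matrix = m, accuracy = sum(diag(m)) / length(pred))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Bins samples into \code{g} quantile groups of predicted probability and
#' compares observed to expected event counts;
#' \eqn{\chi^2 = \sum_k (O_k - E_k)^2 / (E_k (1 - \bar p_k))} on
#' \code{g - 2} degrees of freedom. Bins with identical probability
#' boundaries are merged (with a warning when fewer than \code{g} remain).
#'
#' @param prob predicted probabilities in (0, 1).
#' @param truth binary outcomes.
#' @param g number of bins (>= 3; default 10).
#' @param fitted whether \code{prob} comes from a model fitted on these data
#'   (the default; reference distribution chi-squared on \code{g - 2}
#'   degrees of freedom, the development-data convention). With
#'   \code{fitted = FALSE} — externally specified or validation-cohort
#'   probabilities — no parameters were estimated and the reference uses
#'   \code{g} degrees of freedom.
#' @return List with \code{statistic}, \code{p_value}, \code{df},
#'   \code{bins} (per-bin n, observed, expected).
#' @export
hosmerLemeshow <- function(prob, truth, g = 10L, fitted = TRUE) {
  if (g < 3L) stop("g must be >= 3")
  if (any(prob <= 0) || any(prob >= 1)) stop("prob must lie in (0, 1)")
  truth <- as.integer(truth)
  br <- unique(stats::quantile(prob, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < g + 1L)
    warning("fewer than ", g, " distinct probability bins; merged to ",
            max(length(br) - 1L, 1L))
  if (length(br) < 3L) {  # everything in one bin
    bin <- factor(rep(1L, length(prob)))
  } else {
    bin <- cut(prob, breaks = br, include.lowest = TRUE)
  }
  n_k <- tapply(truth, bin, length)
  O <- tapply(truth, bin, sum)
  E <- tapply(prob, bin, sum)
  pbar <- E / n_k
  den <- E * (1 - pbar)
  terms <- ifelse(den > 0, (O - E)^2 / den,
                  ifelse((O - E)^2 < 1e-16, 0, Inf))
  chi2 <- sum(terms)
  df <- max(nlevels(bin) - (if (fitted) 2L else 0L), 1L)
  list(statistic = chi2, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, bins = data.frame(n = as.vector(n_k), observed = as.vector(O),
                                  expected = as.vector(E)))
}

#' Significance stars
#'
#' One to four asterisks for p below 0.05, 0.01, 0.001 and 0.0001; "ns"
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
significanceStars <- function(p) {
  cuts <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  labs <- c("****", "***", "**", "*", "ns")
  as.character(cut(p, breaks = cuts, labels = labs, right = FALSE))
}
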