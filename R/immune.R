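#' Single-sample GSEA enrichment scores (integral form)
#'
#' For each sample, genes are ranked by expression (descending) and a
#' weighted running sum is walked down the ranking: in-set genes add their
#' absolute-rank weight \eqn{|r|^\alpha} (normalized over in-set genes),
#' out-of-set genes subtract a uniform step. The enrichment score is the sum
#' of the running-sum values over the whole walk (the integral form used for
#' single-sample projection, not the max-deviation statistic), so sets
#' concentrated at the top of a profile score positive and sets at the
#' bottom negative. With \code{alpha = 0} the score depends on ranks only
#' and is invariant to monotone transforms of the profile.
#'
#' @param ue a \linkS4class{UCExperiment}.
#' @param sets named list of gene signatures; each must overlap the matrix
#'   genes but not cover them all (the complement must be non-empty).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize min-max normalize scores across samples within each set
#'   (default \code{FALSE}).
#' @return Long data.frame: \code{sample_id}, \code{feature} (set name),
#'   \code{score}, \code{alpha}.
#' @export
ssgseaScores <- function(ue, sets, alpha = 0.25, normalize = FALSE) {
  if (!is.list(sets)) sets <- list(set = sets)
  v <- exprValues(ue)
  N <- nrow(v)
  out <- lapply(names(sets), function(nm) {
    inset <- rownames(v) %in% sets[[nm]]
    m <- sum(inset)
    if (m == 0L) stop("set '", nm, "' shares no gene with the matrix")
    if (m == N) stop("set '", nm, "' covers every gene (empty complement)")
    es <- vapply(seq_len(ncol(v)), function(j) {
      ord <- order(v[, j], decreasing = TRUE)
      ins <- inset[ord]
      w <- (N:1)^alpha * ins          # absolute ranks N..1, weighted
      inc <- ifelse(ins, w / sum(w), -1 / (N - m))
      sum(cumsum(inc))
    }, numeric(1))
    if (normalize) es <- (es - min(es)) / max(max(es) - min(es), .Machine$double.eps)
    data.frame(sample_id = colnames(v), feature = nm, score = es,
               alpha = alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Marker-mean population scores
#'
#' Per sample and population, the arithmetic mean of the population's marker
#' gene log2 values — an absolute-abundance style score. Populations with no
#' marker present are dropped with a warning.
#'
#' @param ue a \linkS4class{UCExperiment}.
#' @param markerSets named list of marker gene vectors.
#' @return Long data.frame: \code{sample_id}, \code{feature} (population),
#'   \code{score}.
#' @export
markerScores <- function(ue, markerSets) {
  v <- exprValues(ue)
  out <- lapply(names(markerSets), function(nm) {
    genes <- intersect(markerSets[[nm]], rownames(v))
    if (!length(genes)) return(NULL)
    data.frame(sample_id = colnames(v), feature = nm,
               score = colMeans(v[genes, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  dropped <- names(markerSets)[vapply(out, is.null, logical(1))]
  if (length(dropped))
    warning("population(s) with no present marker dropped: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare per-sample scores across molecular subtypes
#'
#' Kruskal-Wallis test of each feature across the subtype groups, BH
#' adjustment across features, and significance stars.
#'
#' @param scores long data.frame with columns \code{sample_id},
#'   \code{feature}, \code{score} (as returned by \code{\link{ssgseaScores}}
#'   or \code{\link{markerScores}}).
#' @param calls subtype calls data.frame with \code{sample_id} and
#'   \code{label} (from \code{\link{subtypeCohort}}); at least 3 subtype
#'   groups must be non-empty.
#' @return data.frame: \code{feature}, \code{H}, \code{p}, \code{q},
#'   \code{stars} — one row per input feature.
#' @export
compareAcrossSubtypes <- function(scores, calls) {
  stopifnot(all(c("sample_id", "feature", "score") %in% colnames(scores)))
  lab <- calls$label[match(scores$sample_id, calls$sample_id)]
  keep <- !is.na(lab)
  scores <- scores[keep, , drop = FALSE]; lab <- droplevels(factor(lab[keep]))
  if (nlevels(lab) < 3L) stop("need >= 3 non-empty subtype groups")
  feats <- unique(scores$feature)
  res <- lapply(feats, function(f) {
    i <- scores$feature == f
    kw <- kruskalWallis(split(scores$score[i], droplevels(lab[i])))
    data.frame(feature = f, H = kw$statistic, p = kw$p_value)
  })
  res <- do.call(rbind, res)
  res$q <- bhAdjust(res$p)
  res$stars <- significanceStars(res$q)
  res
}
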