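#' Rank genes by signal-to-noise between two sample groups
#'
#' Per gene, \eqn{(\mu_A - \mu_B) / (\sigma_A + \sigma_B)} with the usual
#' floor on each group sd (at least 0.2 of the absolute group mean, or 0.2
#' when the mean is 0), sorted descending.
#'
#' @param ue a \linkS4class{UCExperiment}.
#' @param groupA,groupB disjoint sample-id vectors, each of size >= 3.
#' @return Named numeric vector of scores, descending.
#' @export
rankGenes <- function(ue, groupA, groupB) {
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("both groups need >= 3 samples")
  v <- exprValues(ue)
  stopifnot(all(c(groupA, groupB) %in% colnames(v)))
  floorSd <- function(s, m) pmax(s, pmax(0.2 * abs(m), 0.2))
  mA <- rowMeans(v[, groupA, drop = FALSE])
  mB <- rowMeans(v[, groupB, drop = FALSE])
  sA <- floorSd(apply(v[, groupA, drop = FALSE], 1L, stats::sd), mA)
  sB <- floorSd(apply(v[, groupB, drop = FALSE], 1L, stats::sd), mB)
  sort((mA - mB) / (sA + sB), decreasing = TRUE)
}

.esMaxDev <- function(absScores, insetIdx, N) {
  ins <- logical(N); ins[insetIdx] <- TRUE
  w <- absScores * ins
  phit <- cumsum(w) / sum(w)
  pmiss <- cumsum(!ins) / (N - length(insetIdx))
  dev <- phit - pmiss
  unname(dev[which.max(abs(dev))])
}

#' Preranked GSEA with gene-label permutations
#'
#' Weighted Kolmogorov-Smirnov running sum over a ranked gene list (weight
#' \eqn{|score|^1}); the enrichment score is the signed maximum deviation.
#' The null is built by permuting which genes belong to the set (gene-label
#' permutation), NES is ES over the mean absolute same-sign null ES, and the
#' p-value is the same-sign null tail fraction.
#'
#' @param ranked named numeric vector of per-gene ranking scores (sorted
#'   internally, descending).
#' @param set character vector of gene ids; must overlap the ranking but not
#'   cover it.
#' @param nPerm number of permutations (a warning is issued below 100).
#' @param seed integer seed.
#' @return List: \code{ES}, \code{NES}, \code{p_value},
#'   \code{leadingEdge}, \code{size}, \code{nPerm}.
#' @export
gseaPreranked <- function(ranked, set, nPerm = 1000L, seed = 1L) {
  ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  idx <- which(names(ranked) %in% set)
  if (!length(idx)) stop("empty overlap between set and ranking")
  if (length(idx) == N) stop("set covers the whole ranking")
  if (nPerm < 100L) warning("nPerm < 100 gives a coarse null")
  absS <- abs(ranked)
  es <- .esMaxDev(absS, idx, N)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i)
    .esMaxDev(absS, sample.int(N, length(idx)), N), numeric(1))
  same <- null[sign(null) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same)) mean(abs(same) >= abs(es)) else 0
  # leading edge: in-set genes at or before (after, for negative ES) the peak
  ins <- logical(N); ins[idx] <- TRUE
  w <- absS * ins
  dev <- cumsum(w) / sum(w) - cumsum(!ins) / (N - length(idx))
  peak <- which.max(abs(dev))
  le <- if (es >= 0) names(ranked)[seq_len(peak)][ins[seq_len(peak)]]
        else names(ranked)[peak:N][ins[peak:N]]
  list(ES = es, NES = nes, p_value = p, leadingEdge = le,
       size = length(idx), nPerm = nPerm)
}

#' Preranked GSEA over multiple sets with BH adjustment
#'
#' @param ranked named numeric ranking vector.
#' @param sets named list of gene sets.
#' @param nPerm,seed passed to \code{\link{gseaPreranked}}.
#' @return data.frame: set, size, ES, NES, p, q.
#' @export
gseaTable <- function(ranked, sets, nPerm = 1000L, seed = 1L) {
  res <- lapply(names(sets), function(nm) {
    g <- gseaPreranked(ranked, sets[[nm]], nPerm = nPerm, seed = seed)
    data.frame(set = nm, size = g$size, ES = g$ES, NES = g$NES,
               p = g$p_value)
  })
  res <- do.call(rbind, res)
  res$q <- bhAdjust(res$p)
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the overlap between a query gene
#' list and each annotation set (intersected with the universe), with BH
#' adjustment across sets.
#'
#' @param query non-empty gene list, a subset of \code{universe}.
#' @param sets named list of annotation gene sets.
#' @param universe background gene list.
#' @return data.frame: set, overlap, setSize, querySize, universeSize, p, q.
#' @export
oraHypergeometric <- function(query, sets, universe) {
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  universe <- unique(universe); query <- unique(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(s, query))
    p <- stats::phyper(ov - 1L, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, setSize = length(s),
               querySize = length(query), universeSize = length(universe),
               p = p)
  })
  res <- do.call(rbind, res)
  res$q <- bhAdjust(res$p)
  res
}
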