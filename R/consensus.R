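#' Resampling consensus clustering
#'
#' Monti-style consensus clustering of matrix rows: in each of \code{reps}
#' resamples a fraction \code{pItem} of items is drawn, clustered by
#' average-linkage agglomeration on 1 - Pearson correlation distance, and
#' co-clustering counts are accumulated and normalized by co-sampling
#' counts. Item pairs never co-sampled are recorded as \code{NA}, not 0.
#' PAC(k) (proportion of ambiguous clustering) is the consensus CDF
#' difference CDF(0.9) - CDF(0.1) over off-diagonal entries; low PAC marks a
#' clean k.
#'
#' @param x numeric matrix; rows are the items to cluster, columns their
#'   features (e.g. genes x samples). Constant rows are dropped with a
#'   warning.
#' @param kRange integer vector of cluster numbers to evaluate.
#' @param reps number of resamples (>= 20).
#' @param pItem subsampling fraction per resample.
#' @param seed integer seed.
#' @return A \code{ConsensusResult} list: per-k \code{consensus} matrices,
#'   \code{assignments} (from average-linkage clustering of 1 - consensus),
#'   \code{pac}, plus \code{kRange} and \code{seed}.
#' @export
consensusCluster <- function(x, kRange, reps = 100L, pItem = 0.8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (reps < 20L) stop("reps must be >= 20")
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  const <- apply(x, 1L, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s)")
    x <- x[!const, , drop = FALSE]
  }
  n <- nrow(x)
  if (any(kRange >= n)) stop("k must be smaller than the number of items")
  if (any(2L * kRange > n)) stop("need at least 2k items for every k")
  D <- 1 - stats::cor(t(x))
  set.seed(seed)
  m <- floor(pItem * n)
  co_sampled <- matrix(0L, n, n)
  co_clustered <- lapply(kRange, function(k) matrix(0L, n, n))
  names(co_clustered) <- as.character(kRange)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    for (k in kRange) {
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, "==")
      ck <- as.character(k)
      co_clustered[[ck]][idx, idx] <- co_clustered[[ck]][idx, idx] + same
    }
  }
  res <- lapply(as.character(kRange), function(ck) {
    M <- co_clustered[[ck]] / co_sampled   # 0/0 -> NaN where never co-sampled
    M[co_sampled == 0] <- NA_real_
    diag(M) <- 1
    dimnames(M) <- list(rownames(x), rownames(x))
    Mfill <- M
    Mfill[is.na(Mfill)] <- mean(M[upper.tri(M)], na.rm = TRUE)
    hc <- stats::hclust(stats::as.dist(1 - Mfill), method = "average")
    assignments <- stats::cutree(hc, k = as.integer(ck))
    off <- M[upper.tri(M)]
    off <- off[!is.na(off)]
    pac <- mean(off <= 0.9) - mean(off <= 0.1)
    list(consensus = M, assignments = assignments, pac = pac)
  })
  names(res) <- as.character(kRange)
  structure(list(byK = res, kRange = kRange, seed = seed,
                 pac = vapply(res, `[[`, numeric(1), "pac")),
            class = "ConsensusResult")
}

#' Curate co-expressed signature genes by consensus clustering
#'
#' Clusters the signature genes on their expression profiles (consensus
#' clustering at \code{k}, default 3), labels each cluster by the majority
#' signature of its members, and retains the "major subtype-contributing
#' genes": members of the cluster(s) whose majority label matches their own
#' signature. A discordant third cluster is thereby dropped from curation.
#'
#' @param ue a \linkS4class{UCExperiment} (typically UC samples only).
#' @param sigs named list of two gene signatures; the first is treated as
#'   the ferroptosis axis, the second as the neutrophil axis. An error is
#'   raised if fewer than 50\% of a signature's genes are present.
#' @param k number of gene clusters (default 3).
#' @param reps,pItem,seed consensus clustering controls.
#' @param majorityShare minimum fraction of a cluster's members a signature
#'   must hold for the cluster to be assigned to it (default 2/3); clusters
#'   below it are discordant and contribute nothing.
#' @return List with \code{retained} (named list of curated signatures),
#'   \code{clusters} (gene cluster labels), \code{clusterMajority}
#'   (per-cluster signature label or \code{"discordant"}), and the
#'   underlying \code{ConsensusResult}.
#' @export
curateSignatureGenes <- function(ue, sigs, k = 3L, reps = 100L, pItem = 0.8,
                                 seed = 1L, majorityShare = 2 / 3) {
  stopifnot(length(sigs) == 2L, !is.null(names(sigs)))
  v <- exprValues(ue)
  present <- lapply(sigs, intersect, x = rownames(v))
  for (i in seq_along(sigs)) {
    absent <- setdiff(sigs[[i]], rownames(v))
    if (length(absent))
      message(names(sigs)[i], ": ", length(absent), " gene(s) absent")
    if (length(present[[i]]) < 0.5 * length(sigs[[i]]))
      stop("fewer than 50% of '", names(sigs)[i], "' genes present")
  }
  genes <- unique(unlist(present))
  cc <- consensusCluster(v[genes, , drop = FALSE], kRange = k, reps = reps,
                         pItem = pItem, seed = seed)
  cl <- cc$byK[[as.character(k)]]$assignments
  membership <- ifelse(names(cl) %in% present[[1L]], names(sigs)[1L],
                       names(sigs)[2L])
  # genes in both signatures count toward the first (ferroptosis) axis.
  # A cluster is assigned to a signature only when that signature holds a
  # supermajority of its members; mixed clusters are discordant and drop
  # out of curation.
  majority <- vapply(split(membership, cl), function(m) {
    tab <- sort(table(m), decreasing = TRUE)
    if (tab[1L] / sum(tab) >= majorityShare) names(tab)[1L]
    else "discordant"
  }, character(1))
  retained <- lapply(seq_along(sigs), function(i) {
    own <- names(sigs)[i]
    keep_clusters <- names(majority)[majority == own]
    intersect(present[[i]], names(cl)[as.character(cl) %in% keep_clusters])
  })
  names(retained) <- names(sigs)
  list(retained = retained, clusters = cl, clusterMajority = majority,
       consensus = cc)
}
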