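.moduleColors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power the unsigned adjacency \eqn{a_{ij} =
#' |cor(x_i, x_j)|^\beta} is formed, connectivities \eqn{k_i = \sum_{j \ne i}
#' a_{ij}} binned, and the scale-free criterion evaluated as the signed
#' \eqn{R^2} of the regression of \eqn{\log_{10} p(k)} on \eqn{\log_{10} k}
#' (sign flipped when the slope is positive). The smallest power reaching
#' \code{rsqCut} is chosen; if none does, the power with the largest signed
#' \eqn{R^2}.
#'
#' @param ue a \linkS4class{UCExperiment} or a genes x samples matrix with
#'   at least 20 genes.
#' @param powers candidate integer powers (default 1:20).
#' @param rsqCut signed R-squared threshold (default 0.8).
#' @param nBins connectivity histogram bins (default 10).
#' @return List with \code{power} (chosen beta) and \code{table}
#'   (data.frame: power, rsq, slope, meanK) with one row per candidate.
#' @export
pickSoftPower <- function(ue, powers = 1:20, rsqCut = 0.8, nBins = 10L) {
  v <- if (is(ue, "UCExperiment")) exprValues(ue) else as.matrix(ue)
  if (nrow(v) < 20L) stop("need at least 20 genes")
  C <- abs(stats::cor(t(v)))
  diag(C) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    k <- rowSums(C^b)
    br <- seq(min(k), max(k), length.out = nBins + 1L)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    pk <- as.vector(table(bin)) / length(k)
    mk <- tapply(k, bin, mean)
    ok <- pk > 0 & is.finite(mk) & mk > 0
    if (sum(ok) < 3L) return(data.frame(power = b, rsq = NA_real_,
                                        slope = NA_real_, meanK = mean(k)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
    r2 <- summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2L])
    data.frame(power = b, rsq = -sign(slope) * r2, slope = slope,
               meanK = mean(k))
  }))
  hit <- which(!is.na(tab$rsq) & tab$rsq >= rsqCut)
  power <- if (length(hit)) tab$power[hit[1L]] else
    tab$power[which.max(tab$rsq)]
  list(power = power, table = tab)
}

#' Topological overlap matrix
#'
#' \eqn{\Omega_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} for an unsigned adjacency with zeroed
#' diagonal; the diagonal of the result is set to 1. Measures how much two
#' genes share network neighbours.
#'
#' @param adjacency square symmetric matrix with entries in [0, 1].
#' @return TOM similarity matrix of the same dimension.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be square and symmetric")
  if (min(a) < 0 || max(a) > 1) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

.eigengene <- function(zm) {
  # zm: member genes x samples, rows z-scored; first right singular vector,
  # sign fixed so the eigengene tracks the mean member profile
  sv <- svd(zm, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  if (stats::cor(e, colMeans(zm)) < 0) e <- -e
  e
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM with
#' a static branch cut at \code{cutHeight}; clusters smaller than
#' \code{minSize} are relabeled grey (unassigned). Module eigengenes (first
#' principal component of the member genes' z-scored profiles, sign aligned
#' with the mean member profile) are computed and modules whose eigengenes
#' correlate above \code{mergeCor} are iteratively merged. Genes are ordered
#' lexicographically internally so labels do not depend on input order.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param ue \linkS4class{UCExperiment} (or genes x samples matrix) covering
#'   the TOM's genes, used for eigengenes.
#' @param minSize minimum module size (default 10).
#' @param cutHeight static cut height on the 1 - TOM dendrogram
#'   (default 0.99).
#' @param mergeCor eigengene correlation above which modules merge
#'   (default 0.75).
#' @return A \code{ModuleSet} list: \code{labels} (named character; "grey" =
#'   unassigned), \code{eigengenes} (modules x samples), \code{sizes}.
#' @export
detectModules <- function(tom, ue, minSize = 10L, cutHeight = 0.99,
                          mergeCor = 0.75) {
  v <- if (is(ue, "UCExperiment")) exprValues(ue) else as.matrix(ue)
  genes <- sort(rownames(tom))
  tom <- tom[genes, genes]
  v <- v[genes, , drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < minSize])] <- 0L
  if (all(cl == 0L)) {
    warning("no module of size >= ", minSize, "; all genes grey")
    return(structure(list(labels = stats::setNames(rep("grey", length(cl)),
                                                   genes),
                          eigengenes = NULL, sizes = integer()),
                     class = "ModuleSet"))
  }
  zm <- t(scale(t(v)))
  eg <- function(members) .eigengene(zm[members, , drop = FALSE])
  modules <- setdiff(sort(unique(cl)), 0L)
  eigs <- vapply(modules, function(m) eg(names(cl)[cl == m]),
                 numeric(ncol(v)))
  colnames(eigs) <- as.character(modules)
  # merge modules with near-identical eigengenes
  repeat {
    if (ncol(eigs) < 2L) break
    ec <- stats::cor(eigs); diag(ec) <- 0
    mx <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    if (ec[mx[1L], mx[2L]] <= mergeCor) break
    m1 <- colnames(eigs)[mx[1L]]; m2 <- colnames(eigs)[mx[2L]]
    cl[cl == as.integer(m2)] <- as.integer(m1)
    keep <- setdiff(colnames(eigs), m2)
    eigs <- eigs[, keep, drop = FALSE]
    eigs[, m1] <- eg(names(cl)[cl == as.integer(m1)])
  }
  # color labels by decreasing module size
  modules <- names(sort(table(cl[cl != 0L]), decreasing = TRUE))
  colors <- rep_len(.moduleColors, length(modules))
  if (length(modules) > length(.moduleColors))
    colors <- paste0(colors, "_", seq_along(modules))
  map <- stats::setNames(colors, modules)
  labels <- stats::setNames(ifelse(cl == 0L, "grey", map[as.character(cl)]),
                            genes)
  eigengenes <- t(eigs)
  rownames(eigengenes) <- unname(map[rownames(eigengenes)])
  ord <- unname(map[modules])
  eigengenes <- eigengenes[ord, , drop = FALSE]
  colnames(eigengenes) <- colnames(v)
  structure(list(labels = labels, eigengenes = eigengenes,
                 sizes = table(labels)[ord]),
            class = "ModuleSet")
}

#' Module eigengene vs subtype correlation
#'
#' Pearson correlation of every module eigengene with every one-hot subtype
#' indicator, p-values from the t-distribution, BH adjustment over the whole
#' matrix. Degenerate indicators (all samples the same) are skipped.
#'
#' @param moduleSet a \code{ModuleSet} from \code{\link{detectModules}}.
#' @param calls subtype calls (data.frame with \code{sample_id},
#'   \code{label}) covering the eigengene samples; each retained subtype
#'   needs at least 3 samples.
#' @return List of matrices \code{r}, \code{p}, \code{q}
#'   (modules x subtypes).
#' @export
moduleTraitCorrelation <- function(moduleSet, calls) {
  eg <- moduleSet$eigengenes
  if (is.null(eg)) stop("ModuleSet has no eigengenes (all grey)")
  lab <- calls$label[match(colnames(eg), calls$sample_id)]
  if (any(is.na(lab))) stop("calls must cover every eigengene sample")
  levs <- levels(factor(lab))
  keep <- levs[vapply(levs, function(l) {
    x <- as.numeric(lab == l); stats::sd(x) > 0 && sum(x) >= 3
  }, logical(1))]
  if (!length(keep)) stop("no usable subtype indicator")
  r <- p <- matrix(NA_real_, nrow(eg), length(keep),
                   dimnames = list(rownames(eg), keep))
  for (i in seq_len(nrow(eg))) for (l in keep) {
    ct <- correlate(eg[i, ], as.numeric(lab == l), method = "pearson")
    r[i, l] <- ct$r; p[i, l] <- ct$p_value
  }
  q <- matrix(bhAdjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  list(r = r, p = p, q = q)
}
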