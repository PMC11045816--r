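#' Per-sample signature z-score
#'
#' The median, per sample, of the z-scored expression of a signature's
#' genes. The input is expected to be already z-scored by gene (see
#' \code{\link{zscoreByGene}}); signature genes absent from the matrix are
#' ignored, and an error is raised if none is present.
#'
#' @param zue z-scored \linkS4class{UCExperiment}.
#' @param sig character vector of gene ids.
#' @return Named numeric vector, one value per sample.
#' @export
signatureZscores <- function(zue, sig) {
  v <- exprValues(zue)
  genes <- intersect(sig, rownames(v))
  if (!length(genes)) stop("no signature gene present in the matrix")
  apply(v[genes, , drop = FALSE], 2L, stats::median)
}

#' Quadrant subtype from two signature z-scores
#'
#' Deterministic sign rule on the (ferroptosis, neutrophil) median z-score
#' plane: both positive = Mixed, only ferroptosis positive = Ferroptotic,
#' only neutrophil positive = Neutrophilic, neither = Quiescent. Zero counts
#' as "low", so exact boundary points resolve toward Quiescent.
#'
#' @param zFerro,zNeut numeric vectors (recycled to equal length); must be
#'   finite.
#' @return Factor with levels Quiescent, Ferroptotic, Neutrophilic, Mixed.
#' @export
assignQuadrant <- function(zFerro, zNeut) {
  n <- max(length(zFerro), length(zNeut))
  zFerro <- rep_len(zFerro, n); zNeut <- rep_len(zNeut, n)
  if (any(!is.finite(zFerro)) || any(!is.finite(zNeut)))
    stop("z-scores must be finite")
  lab <- ifelse(zFerro > 0,
                ifelse(zNeut > 0, "Mixed", "Ferroptotic"),
                ifelse(zNeut > 0, "Neutrophilic", "Quiescent"))
  factor(lab, levels = c("Quiescent", "Ferroptotic", "Neutrophilic", "Mixed"))
}

#' Subtype a UC cohort by the dual-signature quadrant rule
#'
#' End-to-end subtyping of the UC samples of a cohort: z-score by gene,
#' optionally curate the signature genes by consensus clustering (the
#' default; see \code{\link{curateSignatureGenes}}), compute each sample's
#' median z-score over the two signatures, and assign the quadrant label.
#'
#' @param ue a \linkS4class{UCExperiment}; only samples with
#'   \code{group == "UC"} are subtyped (an error is raised if there are
#'   none).
#' @param sigs named list of two signatures (ferroptosis first, neutrophil
#'   second).
#' @param curate curate signature genes by consensus clustering before
#'   computing the medians (default \code{TRUE}); with \code{FALSE} the full
#'   signatures are used.
#' @param k,reps,pItem,seed curation controls, passed through.
#' @return List with \code{calls} (data.frame: sample_id, z_ferro, z_neut,
#'   label), \code{frequencies} (counts over the four labels, summing to the
#'   number of UC samples), and \code{retained} signatures.
#' @export
subtypeCohort <- function(ue, sigs, curate = TRUE, k = 3L, reps = 100L,
                          pItem = 0.8, seed = 1L) {
  stopifnot(length(sigs) == 2L)
  uc <- ue[, sampleMeta(ue)$group == "UC"]
  if (ncol(uc) == 0L) stop("cohort contains no UC samples")
  if (ncol(uc) == 1L) {
    # degenerate single-sample cohort: z-scores are undefined; call Quiescent
    calls <- data.frame(sample_id = colnames(uc), z_ferro = 0, z_neut = 0,
                        label = assignQuadrant(0, 0))
    return(list(calls = calls, frequencies = table(calls$label),
                retained = sigs))
  }
  zue <- zscoreByGene(uc)
  retained <- sigs
  if (curate) {
    cur <- curateSignatureGenes(zue, sigs, k = k, reps = reps, pItem = pItem,
                                seed = seed)
    # fall back to the full list if curation empties a signature
    retained <- mapply(function(r, s) if (length(r)) r else s,
                       cur$retained, sigs, SIMPLIFY = FALSE)
  }
  zF <- signatureZscores(zue, retained[[1L]])
  zN <- signatureZscores(zue, retained[[2L]])
  calls <- data.frame(sample_id = colnames(zue), z_ferro = unname(zF),
                      z_neut = unname(zN),
                      label = assignQuadrant(zF, zN))
  list(calls = calls, frequencies = table(calls$label), retained = retained)
}
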