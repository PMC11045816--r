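#' Responder vs non-responder analysis of hub genes
#'
#' For each gene and timepoint, compares expression between responders (R)
#' and non-responders (NR) by the Wilcoxon rank-sum test (BH-adjusted across
#' genes within each timepoint) and reports the per-gene discrimination AUC
#' using expression as the score, oriented so AUC >= 0.5, with the direction
#' of the shift. Pre- and post-treatment timepoints are analyzed
#' independently.
#'
#' @param ue a \linkS4class{UCExperiment} whose \code{colData} carries
#'   \code{response} (\code{R}/\code{NR}) and \code{timepoint}
#'   (\code{pre}/\code{post}); each timepoint needs >= 3 samples per arm.
#' @param genes gene ids to report (must be present in the matrix).
#' @return data.frame with one row per (gene, timepoint): \code{gene},
#'   \code{timepoint}, \code{p}, \code{q}, \code{auc}, \code{direction}
#'   (\code{"up_in_R"}/\code{"down_in_R"}).
#' @export
responseAnalysis <- function(ue, genes) {
  meta <- sampleMeta(ue)
  if (!all(c("response", "timepoint") %in% colnames(meta)) ||
      any(is.na(meta$timepoint)))
    stop("colData must provide complete 'response' and 'timepoint' labels")
  v <- exprValues(ue)
  missing_g <- setdiff(genes, rownames(v))
  if (length(missing_g))
    stop("gene(s) absent: ", paste(missing_g, collapse = ", "))
  out <- lapply(unique(meta$timepoint), function(tp) {
    sel <- meta$timepoint == tp
    resp <- meta$response[sel]
    if (sum(resp == "R") < 3L || sum(resp == "NR") < 3L)
      stop("timepoint '", tp, "' needs >= 3 R and >= 3 NR samples")
    rows <- lapply(genes, function(g) {
      x <- v[g, sel]
      w <- wilcoxonRankSum(x[resp == "R"], x[resp == "NR"])
      auc0 <- rocAuc(x, resp == "R")$auc
      data.frame(gene = g, timepoint = tp, p = w$p_value,
                 auc = max(auc0, 1 - auc0),
                 direction = if (auc0 >= 0.5) "up_in_R" else "down_in_R",
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bhAdjust(tab$p)
    tab
  })
  res <- do.call(rbind, out)
  res[, c("gene", "timepoint", "p", "q", "auc", "direction")]
}
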