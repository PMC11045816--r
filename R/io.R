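#' Read an expression matrix with sample annotation
#'
#' Reads a genes x samples TSV/CSV (gene ids in the first column, sample ids
#' in the header) together with an annotation table keyed by \code{sample_id},
#' and returns a validated \linkS4class{UCExperiment}. The field separator is
#' taken from the file extension (\code{.csv} = comma, otherwise tab).
#'
#' @param path expression matrix file.
#' @param annotPath annotation TSV with mandatory columns \code{sample_id} and
#'   \code{group}; optional \code{batch}, \code{response}, \code{timepoint}.
#' @return A \linkS4class{UCExperiment}; zero-variance genes are flagged in
#'   \code{rowData(ue)$zero_variance}.
#' @export
readExpression <- function(path, annotPath) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- ids
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  storage.mode(values) <- "double"
  meta <- utils::read.table(annotPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("annotation must contain 'sample_id' and 'group' columns")
  UCExperiment(values, meta)
}

#' Write an expression matrix and its annotation
#'
#' Inverse of \code{\link{readExpression}}: full-precision TSV round-trip.
#'
#' @param ue a \linkS4class{UCExperiment}.
#' @param path output expression TSV path.
#' @param annotPath output annotation TSV path (skipped if \code{NULL}).
#' @export
writeExpression <- function(ue, path, annotPath = NULL) {
  v <- exprValues(ue)
  df <- data.frame(gene_id = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotPath)) {
    meta <- sampleMeta(ue)
    meta <- cbind(sample_id = rownames(meta), meta)
    utils::write.table(meta, annotPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated \code{name}, description
#' (discarded), then gene ids. Duplicate genes within a set are dropped.
#'
#' @param path GMT file.
#' @return Named list of character vectors (one per signature). An empty file
#'   yields an empty list.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    out[[f[[1L]]]] <- unique(f[-c(1L, 2L)])
  }
  out
}

#' Write gene signatures to a GMT file
#'
#' @param sigs named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of description fields.
#' @export
writeGmt <- function(sigs, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sigs))
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], descriptions[i], sigs[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Z-score each gene across samples
#'
#' Centers and scales every gene row to mean 0 / sd 1. Zero-variance genes
#' cannot be scaled and are dropped with a warning. The per-sample signature
#' median ("signature z-score") used for quadrant subtyping is computed on
#' this scale.
#'
#' @param ue a \linkS4class{UCExperiment} with at least 2 samples.
#' @return A \linkS4class{UCExperiment} of z-scored values.
#' @export
zscoreByGene <- function(ue) {
  v <- exprValues(ue)
  if (ncol(v) < 2L) stop("z-scoring requires at least 2 samples")
  sds <- apply(v, 1L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance gene(s): ",
            paste(utils::head(rownames(v)[!keep], 5L), collapse = ", "))
    v <- v[keep, , drop = FALSE]
    sds <- sds[keep]
  }
  z <- (v - rowMeans(v)) / sds
  UCExperiment(z, sampleMeta(ue))
}

#' Remove additive/multiplicative batch effects
#'
#' Location-scale batch adjustment with empirical-Bayes shrinkage of
#' per-batch gene means and variances toward pooled priors, then
#' back-transformation onto the original scale (the ComBat model; the
#' adjustment is delegated to \code{sva::ComBat}). With a single batch the
#' input is returned unchanged with a warning.
#'
#' @param ue a \linkS4class{UCExperiment} whose \code{colData} has a
#'   \code{batch} column; every batch needs at least 2 samples.
#' @param parametric use the parametric normal / inverse-gamma priors
#'   (default) rather than the nonparametric empirical priors.
#' @return Batch-adjusted \linkS4class{UCExperiment}.
#' @export
batchCorrect <- function(ue, parametric = TRUE) {
  meta <- sampleMeta(ue)
  if (!("batch" %in% colnames(meta)))
    stop("colData must contain a 'batch' column")
  batch <- as.character(meta$batch)
  nb <- table(batch)
  if (length(nb) == 1L) {
    warning("single batch: returning input unchanged")
    return(ue)
  }
  if (any(nb < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  v <- exprValues(ue)
  # ComBat cannot standardize genes that are constant within every batch
  adj <- suppressMessages(
    sva::ComBat(dat = v, batch = batch, par.prior = parametric,
                prior.plots = FALSE))
  UCExperiment(adj, meta)
}
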