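#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' UCExperiment: log2 expression with per-sample annotation
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{log2} assay (genes in rows, samples in columns) plus per-sample
#' metadata in \code{colData}. Validity enforces the container contract:
#' unique gene and sample identifiers, all values finite, and a \code{group}
#' column with levels \code{UC} / \code{HC}. Optional columns \code{batch},
#' \code{response} (\code{R}/\code{NR}) and \code{timepoint}
#' (\code{pre}/\code{post}) are checked when present.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @export
setClass("UCExperiment", contains = "SummarizedExperiment")

.validUCExperiment <- function(object) {
  msg <- character()
  if (!("log2" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'log2' is required")
  v <- SummarizedExperiment::assay(object, "log2")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!all(is.finite(v)))
    msg <- c(msg, "expression values must all be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!("group" %in% colnames(cd))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(cd$group %in% c("UC", "HC"))) {
    msg <- c(msg, "group must be 'UC' or 'HC'")
  }
  if ("response" %in% colnames(cd)) {
    ok <- is.na(cd$response) | cd$response %in% c("R", "NR")
    if (!all(ok)) msg <- c(msg, "response must be 'R', 'NR' or NA")
  }
  if ("timepoint" %in% colnames(cd)) {
    ok <- is.na(cd$timepoint) | cd$timepoint %in% c("pre", "post")
    if (!all(ok)) msg <- c(msg, "timepoint must be 'pre', 'post' or NA")
  }
  if (length(msg)) msg else TRUE
}

setValidity("UCExperiment", .validUCExperiment)

#' Construct a UCExperiment
#'
#' @param values numeric matrix, genes x samples, log2 scale, with rownames
#'   (gene ids) and colnames (sample ids).
#' @param meta data.frame of per-sample annotation with at least a
#'   \code{group} column (\code{UC}/\code{HC}); rows are matched to
#'   \code{colnames(values)} by its \code{sample_id} column if present,
#'   otherwise by row order.
#' @return A \linkS4class{UCExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ue <- UCExperiment(m, data.frame(group = c("UC", "UC", "HC", "HC")))
#' @export
UCExperiment <- function(values, meta) {
  values <- as.matrix(values)
  if (max(values, na.rm = TRUE) > 50)
    warning("matrix maximum exceeds 50; input looks linear-scale, not log2")
  meta <- as.data.frame(meta)
  if ("sample_id" %in% colnames(meta)) {
    if (!setequal(meta$sample_id, colnames(values))) {
      missing_ann <- setdiff(colnames(values), meta$sample_id)
      extra_ann <- setdiff(meta$sample_id, colnames(values))
      stop("annotation/sample mismatch; missing annotation for: ",
           paste(missing_ann, collapse = ", "),
           if (length(extra_ann)) paste0("; annotated but absent: ",
                                         paste(extra_ann, collapse = ", ")))
    }
    meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
    rownames(meta) <- meta$sample_id
    meta$sample_id <- NULL
  } else {
    stopifnot(nrow(meta) == ncol(values))
    rownames(meta) <- colnames(values)
  }
  zv <- apply(values, 1L, stats::sd) == 0
  rd <- S4Vectors::DataFrame(zero_variance = zv, row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(meta),
    rowData = rd)
  new("UCExperiment", se)
}

#' @describeIn UCExperiment expression matrix accessor (genes x samples)
#' @param ue a \code{UCExperiment}
#' @export
exprValues <- function(ue) SummarizedExperiment::assay(ue, "log2")

#' @describeIn UCExperiment per-sample annotation as a data.frame
#' @export
sampleMeta <- function(ue) as.data.frame(SummarizedExperiment::colData(ue))

setMethod("show", "UCExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("UCExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(cd$group)),
                                 table(cd$group)), collapse = " "), "\n")
  if ("batch" %in% colnames(cd))
    cat("  batches:", length(unique(cd$batch)), "\n")
  invisible(NULL)
})

#' DiagnosticModel: binarized-score neural diagnostic
#'
#' Holds the hub-gene encoding (per-gene cohort median and disease-typical
#' direction) and the weights of a single-hidden-layer logistic network
#' mapping the 0/1 gene scores to a UC probability.
#'
#' @slot genes character, hub gene ids (network inputs, in order).
#' @slot medians numeric, per-gene encoding threshold (training-cohort median).
#' @slot directions character, per-gene \code{"up_in_UC"} or \code{"down_in_UC"}.
#' @slot W1 numeric matrix, hidden x (inputs + 1); column 1 is the bias.
#' @slot W2 numeric matrix, 1 x (hidden + 1); column 1 is the bias.
#' @slot threshold numeric scalar decision threshold on the output probability.
#' @export
setClass("DiagnosticModel",
         representation(genes = "character", medians = "numeric",
                        directions = "character", W1 = "matrix",
                        W2 = "matrix", threshold = "numeric"))

setValidity("DiagnosticModel", function(object) {
  p <- length(object@genes)
  msg <- character()
  if (length(object@medians) != p || length(object@directions) != p)
    msg <- c(msg, "one median and one direction per hub gene required")
  if (!all(object@directions %in% c("up_in_UC", "down_in_UC")))
    msg <- c(msg, "directions must be 'up_in_UC' or 'down_in_UC'")
  if (ncol(object@W1) != p + 1L)
    msg <- c(msg, "W1 must have one column per input plus a bias column")
  if (nrow(object@W2) != 1L || ncol(object@W2) != nrow(object@W1) + 1L)
    msg <- c(msg, "W2 must be 1 x (hidden + 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosticModel", function(object) {
  cat("DiagnosticModel:", length(object@genes), "input genes,",
      nrow(object@W1), "hidden units\n")
  cat("  genes:", paste(object@genes, collapse = ", "), "\n")
  cat("  threshold:", object@threshold, "\n")
  invisible(NULL)
})

#' @describeIn DiagnosticModel hub genes used as network inputs
#' @param model a \code{DiagnosticModel}
#' @export
modelGenes <- function(model) model@genes
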