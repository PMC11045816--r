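#' Specify a synthetic UC/HC cohort
#'
#' Describes a merged multi-batch cohort of UC and healthy (HC) mucosal
#' transcriptomes with planted structure: two co-expression programs (a
#' 64-gene ferroptosis program and a 34-gene neutrophil program) whose
#' high/low activity defines four latent UC subtypes, hub genes shifted
#' between UC and HC, responder-coupled genes, and additive/multiplicative
#' batch effects. Defaults mirror the merged GEO cohort the subtyping scheme
#' was developed on: 298 UC and 55 HC samples over 3 batches, subtype
#' mixture (77, 90, 77, 54)/298 for quiescent/ferroptotic/neutrophilic/
#' mixed, program activation effect 1.5 (log2 units), within-program
#' correlation 0.5, unit noise sd.
#'
#' @param nUC,nHC sample counts.
#' @param mixture named subtype probabilities over Quiescent, Ferroptotic,
#'   Neutrophilic, Mixed; must sum to 1 (tolerance 1e-9).
#' @param nFerro,nNeut program sizes (the two hub genes of each program are
#'   counted inside them).
#' @param rho target within-program Pearson correlation among UC samples.
#'   Subtype activation itself covaries all of a program's genes, so the
#'   shared-factor loading is derived by subtracting the activation-driven
#'   covariance from the target; the factor supplies only the remainder
#'   (and is dropped, with a message, if activation alone already exceeds
#'   the target).
#' @param dProg activation shift (log2 units) added to a program's genes in
#'   samples whose subtype activates it.
#' @param nNull number of unstructured background genes.
#' @param hubGenes four planted diagnostic genes (first two belong to the
#'   ferroptosis program, last two to the neutrophil program).
#' @param dDiag UC-vs-HC shift applied to hub genes.
#' @param hubDirections per-hub \code{"up_in_UC"} / \code{"down_in_UC"}.
#' @param responderFraction fraction of UC patients who respond to therapy.
#' @param dResp responder-vs-nonresponder shift on \code{responseGenes}.
#' @param responseGenes genes coupled to response (default: the two
#'   neutrophil-program hubs).
#' @param nPatients number of treated patients in the paired pre/post design.
#' @param recovery fraction of the disease deviation removed in responders'
#'   post-treatment samples.
#' @param nBatches number of batches; \code{batchShiftSd} is the sd of the
#'   per-batch-per-gene additive shift, \code{batchScaleSdLog} the sdlog of
#'   the lognormal multiplicative scale.
#' @param noiseSd residual sd (log2 units).
#' @param seed integer seed (mandatory; the generator is fully reproducible).
#' @return A \code{CohortSpec} list.
#' @export
cohortSpec <- function(nUC = 298L, nHC = 55L,
                       mixture = c(Quiescent = 77, Ferroptotic = 90,
                                   Neutrophilic = 77, Mixed = 54) / 298,
                       nFerro = 64L, nNeut = 34L, rho = 0.5, dProg = 1.5,
                       nNull = 200L,
                       hubGenes = c("FTH1", "STEAP3", "AQP9", "STEAP4"),
                       dDiag = 1.5,
                       hubDirections = rep("up_in_UC", 4L),
                       responderFraction = 0.5, dResp = 1.5,
                       responseGenes = hubGenes[3:4],
                       nPatients = 24L, recovery = 0.7,
                       nBatches = 3L, batchShiftSd = 1, batchScaleSdLog = 0.25,
                       noiseSd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(mixture) - 1) > 1e-9) stop("subtype mixture must sum to 1")
  stopifnot(length(hubGenes) == 4L, length(hubDirections) == 4L,
            all(hubDirections %in% c("up_in_UC", "down_in_UC")),
            rho >= 0, rho < 1, noiseSd > 0)
  spec <- list(nUC = as.integer(nUC), nHC = as.integer(nHC),
               mixture = mixture, nFerro = as.integer(nFerro),
               nNeut = as.integer(nNeut), rho = rho, dProg = dProg,
               nNull = as.integer(nNull), hubGenes = hubGenes, dDiag = dDiag,
               hubDirections = hubDirections,
               responderFraction = responderFraction, dResp = dResp,
               responseGenes = responseGenes, nPatients = as.integer(nPatients),
               recovery = recovery, nBatches = as.integer(nBatches),
               batchShiftSd = batchShiftSd, batchScaleSdLog = batchScaleSdLog,
               noiseSd = noiseSd, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

.geneTable <- function(spec) {
  ferro <- c(spec$hubGenes[1:2],
             sprintf("FERRO_%03d", seq_len(spec$nFerro - 2L)))
  neut <- c(spec$hubGenes[3:4],
            sprintf("NEUT_%03d", seq_len(spec$nNeut - 2L)))
  null <- sprintf("NULL_%03d", seq_len(spec$nNull))
  genes <- data.frame(
    gene_id = c(ferro, neut, null),
    program = rep(c("ferro", "neut", "null"),
                  c(spec$nFerro, spec$nNeut, spec$nNull)),
    stringsAsFactors = FALSE)
  genes$is_hub <- genes$gene_id %in% spec$hubGenes
  genes$direction <- NA_character_
  genes$direction[genes$is_hub] <-
    spec$hubDirections[match(genes$gene_id[genes$is_hub], spec$hubGenes)]
  genes
}

# factor loading^2 that realizes the target within-program correlation in
# the UC cohort, once the activation-driven covariance p(1-p) d^2 is
# accounted for: (s^2 rho0 + vAct) / (s^2 + vAct) = rho
.factorVarShare <- function(rho, pAct, dProg, noiseSd) {
  vAct <- pAct * (1 - pAct) * dProg^2
  rho0 <- (rho * (noiseSd^2 + vAct) - vAct) / noiseSd^2
  if (rho0 < 0) {
    message("activation covariance alone exceeds target rho; ",
            "shared factor dropped")
    rho0 <- 0
  }
  min(rho0, 1)
}

# latent-factor program values: sqrt(rho0) shared factor + sqrt(1-rho0)
# idiosyncratic noise, scaled by noiseSd; O(genes) and positive definite
.programBlock <- function(nGenes, factor_s, rho0, noiseSd) {
  n <- length(factor_s)
  eps <- matrix(stats::rnorm(nGenes * n), nGenes, n)
  noiseSd * (sqrt(rho0) * matrix(factor_s, nGenes, n, byrow = TRUE) +
               sqrt(1 - rho0) * eps)
}

.applyBatch <- function(v, mu, batch, spec) {
  for (b in unique(batch)) {
    idx <- which(batch == b)
    gamma <- stats::rnorm(nrow(v), 0, spec$batchShiftSd)
    delta <- stats::rlnorm(nrow(v), 0, spec$batchScaleSdLog)
    v[, idx] <- mu + gamma + delta * (v[, idx] - mu)
  }
  v
}

#' Generate a synthetic UC/HC cohort with planted truth
#'
#' Draws a cohort per \code{\link{cohortSpec}}: baseline gene means
#' ~ N(7, 1) on the log2 scale; program genes share a latent factor (loading
#' sqrt(rho)); subtypes activate programs (+\code{dProg} on the ferroptosis
#' program for Ferroptotic, the neutrophil program for Neutrophilic, both
#' for Mixed, neither for Quiescent; HC samples never activate); hub genes
#' are shifted by \code{dDiag} in UC relative to HC; batch location/scale
#' effects are applied last.
#'
#' @param spec a \code{CohortSpec}.
#' @return List with \code{ue} (a \linkS4class{UCExperiment}) and
#'   \code{truth} (list of \code{samples} and \code{genes} data.frames).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$nUC + spec$nHC
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("UC", "HC"), c(spec$nUC, spec$nHC))
  subtype <- rep(NA_character_, n)
  subtype[group == "UC"] <- sample(names(spec$mixture), spec$nUC,
                                   replace = TRUE, prob = spec$mixture)
  batch <- paste0("B", sample.int(spec$nBatches, n, replace = TRUE))
  genes <- .geneTable(spec)
  mu <- stats::rnorm(nrow(genes), 7, 1)
  names(mu) <- genes$gene_id

  actF <- as.numeric(subtype %in% c("Ferroptotic", "Mixed"))
  actN <- as.numeric(subtype %in% c("Neutrophilic", "Mixed"))
  fF <- stats::rnorm(n); fN <- stats::rnorm(n)

  pF <- sum(spec$mixture[c("Ferroptotic", "Mixed")])
  pN <- sum(spec$mixture[c("Neutrophilic", "Mixed")])
  rho0F <- .factorVarShare(spec$rho, pF, spec$dProg, spec$noiseSd)
  rho0N <- .factorVarShare(spec$rho, pN, spec$dProg, spec$noiseSd)

  v <- matrix(0, nrow(genes), n, dimnames = list(genes$gene_id, sample_id))
  iF <- genes$program == "ferro"; iN <- genes$program == "neut"
  iZ <- genes$program == "null"
  v[iF, ] <- .programBlock(sum(iF), fF, rho0F, spec$noiseSd) +
    spec$dProg * matrix(actF, sum(iF), n, byrow = TRUE)
  v[iN, ] <- .programBlock(sum(iN), fN, rho0N, spec$noiseSd) +
    spec$dProg * matrix(actN, sum(iN), n, byrow = TRUE)
  v[iZ, ] <- matrix(stats::rnorm(sum(iZ) * n, 0, spec$noiseSd), sum(iZ), n)

  sgn <- ifelse(spec$hubDirections == "up_in_UC", 1, -1)
  isUC <- as.numeric(group == "UC")
  for (h in seq_along(spec$hubGenes))
    v[spec$hubGenes[h], ] <- v[spec$hubGenes[h], ] +
      sgn[h] * spec$dDiag * isUC
  v <- v + mu
  v <- .applyBatch(v, mu, batch, spec)

  meta <- data.frame(sample_id = sample_id, group = group, batch = batch,
                     stringsAsFactors = FALSE)
  ue <- UCExperiment(v, meta)
  truth_s <- data.frame(sample_id = sample_id, group = group, batch = batch,
                        subtype = subtype, stringsAsFactors = FALSE)
  list(ue = ue, truth = list(samples = truth_s, genes = genes))
}

#' Generate a paired pre/post treatment-response cohort
#'
#' Emulates an infliximab response design: \code{nPatients} UC patients each
#' sampled before and after first treatment, plus \code{nHC} healthy
#' controls as reference. Response-coupled genes are shifted by \code{dResp}
#' in responders at the pre timepoint; in responders' post samples the whole
#' disease deviation (hub shifts, program activation, coupling) is scaled by
#' \code{1 - recovery}, moving expression toward the healthy baseline.
#' Non-responders keep their deviation at post.
#'
#' @param spec a \code{CohortSpec}; \code{responderFraction} must lie
#'   strictly in (0, 1).
#' @return List with \code{ue} and \code{truth$samples} (patient ids, paired
#'   timepoints, response), \code{truth$genes}.
#' @export
generateResponseCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$responderFraction <= 0 || spec$responderFraction >= 1)
    stop("responderFraction must lie strictly in (0, 1)")
  set.seed(spec$seed + 1L)
  np <- spec$nPatients
  nR <- round(np * spec$responderFraction)
  response <- sample(rep(c("R", "NR"), c(nR, np - nR)))
  genes <- .geneTable(spec)
  mu <- stats::rnorm(nrow(genes), 7, 1)

  # per-patient systematic disease deviation (shared by pre and post)
  subtype <- sample(names(spec$mixture), np, replace = TRUE,
                    prob = spec$mixture)
  dev <- matrix(0, nrow(genes), np)
  dev[genes$program == "ferro", ] <- spec$dProg *
    matrix(as.numeric(subtype %in% c("Ferroptotic", "Mixed")),
           sum(genes$program == "ferro"), np, byrow = TRUE)
  dev[genes$program == "neut", ] <- spec$dProg *
    matrix(as.numeric(subtype %in% c("Neutrophilic", "Mixed")),
           sum(genes$program == "neut"), np, byrow = TRUE)
  sgn <- ifelse(spec$hubDirections == "up_in_UC", 1, -1)
  for (h in seq_along(spec$hubGenes))
    dev[genes$gene_id == spec$hubGenes[h], ] <-
      dev[genes$gene_id == spec$hubGenes[h], ] + sgn[h] * spec$dDiag
  iResp <- genes$gene_id %in% spec$responseGenes
  dev[iResp, response == "R"] <- dev[iResp, response == "R"] + spec$dResp

  noise <- function() matrix(stats::rnorm(nrow(genes) * np, 0, spec$noiseSd),
                             nrow(genes), np)
  pre <- mu + dev + noise()
  post_dev <- dev
  post_dev[, response == "R"] <- (1 - spec$recovery) * dev[, response == "R"]
  post <- mu + post_dev + noise()

  v <- cbind(pre, post)
  pid <- sprintf("P%03d", seq_len(np))
  colnames(v) <- c(paste0(pid, "_pre"), paste0(pid, "_post"))
  rownames(v) <- genes$gene_id
  meta <- data.frame(
    sample_id = colnames(v),
    group = "UC",
    patient = rep(pid, 2L),
    response = rep(response, 2L),
    timepoint = rep(c("pre", "post"), each = np),
    stringsAsFactors = FALSE)
  ue <- UCExperiment(v, meta)
  list(ue = ue,
       truth = list(samples = meta[, c("sample_id", "patient", "response",
                                       "timepoint")],
                    genes = genes))
}

#' Signatures of the planted programs
#'
#' Convenience accessor: the ferroptosis and neutrophil gene lists of a
#' synthetic cohort, as a named list suitable for every signature-consuming
#' operation (and for \code{\link{writeGmt}}).
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateCohort}}.
#' @return List with elements \code{ferroptosis} and \code{neutrophil}.
#' @export
truthSignatures <- function(truth) {
  g <- truth$genes
  list(ferroptosis = g$gene_id[g$program == "ferro"],
       neutrophil = g$gene_id[g$program == "neut"])
}
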