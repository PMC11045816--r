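# Shared fixtures, built in code at test time.

# small UCExperiment with explicit values
tinyUE <- function(values = NULL, group = NULL) {
  if (is.null(values))
    values <- matrix(c(1, 2, 3, 4,
                       4, 3, 2, 1,
                       2, 2, 5, 5), 3, 4, byrow = TRUE,
                     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  if (is.null(group)) group <- c("UC", "UC", "HC", "HC")
  UCExperiment(values, data.frame(group = group))
}

# equicorrelated planted blocks: nb blocks of `per` items over nf features
plantedBlocks <- function(seed, nb = 3, per = 30, nf = 60, rho = 0.8,
                          nNoise = 0) {
  set.seed(seed)
  blocks <- do.call(rbind, lapply(seq_len(nb), function(b) {
    f <- rnorm(nf)
    t(vapply(seq_len(per),
             function(g) sqrt(rho) * f + sqrt(1 - rho) * rnorm(nf),
             numeric(nf)))
  }))
  out <- rbind(blocks,
               if (nNoise) matrix(rnorm(nNoise * nf), nNoise, nf))
  rownames(out) <- c(sprintf("blk%d_g%02d", rep(seq_len(nb), each = per),
                             rep(seq_len(per), nb)),
                     if (nNoise) sprintf("noise%02d", seq_len(nNoise)))
  colnames(out) <- sprintf("s%02d", seq_len(nf))
  out
}

# heterogeneous modular network: blocks of varying size and tightness plus
# unstructured genes, so connectivity spreads over a wide range
plantedHetNetwork <- function(seed, n = 80, nNoise = 40,
                              sizes = c(40, 25, 15, 10),
                              rhos = c(0.85, 0.7, 0.55, 0.4)) {
  set.seed(seed)
  blocks <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    f <- rnorm(n)
    t(vapply(seq_len(sizes[b]),
             function(g) sqrt(rhos[b]) * f + sqrt(1 - rhos[b]) * rnorm(n),
             numeric(n)))
  }))
  v <- rbind(blocks, matrix(rnorm(nNoise * n), nNoise, n))
  rownames(v) <- paste0("g", seq_len(nrow(v)))
  colnames(v) <- paste0("s", seq_len(n))
  v
}

# the standard synthetic cohort (generated once per test run)
.stdCohortCache <- new.env()
stdCohort <- function(seed = 1L, ...) {
  key <- paste0("c", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.stdCohortCache[[key]])) {
    ch <- generateCohort(cohortSpec(seed = seed, ...))
    ch$ueCorrected <- suppressWarnings(batchCorrect(ch$ue))
    .stdCohortCache[[key]] <- ch
  }
  .stdCohortCache[[key]]
}

quadrantRecovery <- function(ch, calls) {
  tr <- ch$truth$samples
  uc <- tr[tr$group == "UC", ]
  mean(as.character(calls$label) ==
         uc$subtype[match(calls$sample_id, uc$sample_id)])
}
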