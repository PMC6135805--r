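#' Simulate a two-population RNA-seq count study with planted signal
#'
#' Counts are negative binomial with gene-specific baselines (variance
#' `mu + dispersion * mu^2`), multiplicative library sizes drawn log-uniform
#' within `libSizeRange`, additive-in-log2 batch shifts (per gene, shared by
#' all samples of a batch, SD `batchEffectSd`), and planted signed log2
#' fold-changes of magnitude `lfcScale` between the two populations.
#' Neighbors of the planted factor nodes are differentially expressed with
#' probability `neighborDeProb`, all other genes with `backgroundDeProb`,
#' which is what ties the interactome hubs to the transcriptome signal.
#'
#' The gene universe contains every network node plus synthetic filler genes
#' up to `nGenes`. Batches are assigned round-robin within each population so
#' batch and population are never confounded.
#'
#' @param network a [PPINetwork-class]; its nodes enter the gene universe.
#' @param factors character vector of planted factor nodes (see
#'   [plantFactors()]).
#' @param nGenes total genes to simulate (>= number of network nodes).
#' @param samplesPerGroup integer pair: samples in each population.
#' @param neighborDeProb,backgroundDeProb DE probability for factor neighbors
#'   and for all remaining genes.
#' @param lfcScale magnitude (log2 units) of planted fold-changes.
#' @param dispersion NB dispersion phi (constant across genes); 0 gives
#'   Poisson counts.
#' @param libSizeRange numeric pair; library sizes are drawn log-uniform in
#'   this range.
#' @param batchEffectSd SD (log2 units) of the per-gene batch shifts.
#' @param nBatches number of batches.
#' @param seed integer seed.
#' @param groupLabels the two population labels.
#' @return list with elements `study` (a [CountStudy-class]) and `truth`
#'   (a [SyntheticTruth-class]).
#' @export
generateCounts <- function(network, factors, nGenes = 2000,
                           samplesPerGroup = c(8, 4),
                           neighborDeProb = 0.5, backgroundDeProb = 0.05,
                           lfcScale = 1.5, dispersion = 0.1,
                           libSizeRange = c(5e5, 2e6),
                           batchEffectSd = 1, nBatches = 2, seed = 11,
                           groupLabels = c("bloodASC", "bmLLPC")) {
  if (any(samplesPerGroup <= 0)) stop("samplesPerGroup must be positive")
  if (length(samplesPerGroup) != 2) stop("samplesPerGroup must have length 2")
  for (p in c(neighborDeProb, backgroundDeProb))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  nodes <- ppiNodes(network)
  if (nGenes < length(nodes))
    stop("nGenes must cover all network nodes (", length(nodes), ")")
  if (!all(factors %in% nodes)) stop("factors must be network nodes")

  withr::with_seed(seed, {
    extra <- setdiff(sprintf("G%06d", seq_len(nGenes + length(nodes))), nodes)
    genes <- c(nodes, extra[seq_len(nGenes - length(nodes))])
    nbrs <- unionPartners(expandSeeds(network, factors))
    isNbr <- genes %in% nbrs

    de <- rbinom(nGenes, 1, ifelse(isNbr, neighborDeProb, backgroundDeProb)) == 1
    lfc <- numeric(nGenes)
    lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) * lfcScale

    n1 <- samplesPerGroup[1]; n2 <- samplesPerGroup[2]
    n <- n1 + n2
    pop <- rep(groupLabels, c(n1, n2))
    samples <- sprintf("S%02d", seq_len(n))
    batch <- unlist(lapply(samplesPerGroup, function(k)
      sprintf("batch%d", ((seq_len(k) - 1) %% nBatches) + 1)))
    libSize <- exp(runif(n, log(libSizeRange[1]), log(libSizeRange[2])))

    base <- rnorm(nGenes, 0, 1.8)           # log2 relative abundance
    w1 <- 2^base
    w2 <- 2^(base + lfc)                    # fold-change applied to group 2
    p1 <- w1 / sum(w1)
    p2 <- w2 / sum(w2)

    delta <- matrix(rnorm(nGenes * nBatches, 0, batchEffectSd),
                    nrow = nGenes,
                    dimnames = list(NULL, sprintf("batch%d", seq_len(nBatches))))

    mu <- matrix(0, nGenes, n)
    for (j in seq_len(n)) {
      pj <- if (pop[j] == groupLabels[1]) p1 else p2
      mu[, j] <- libSize[j] * pj * 2^delta[, batch[j]]
    }
    counts <- if (dispersion > 0) {
      matrix(rnbinom(nGenes * n, mu = mu, size = 1 / dispersion), nGenes, n)
    } else {
      matrix(rpois(nGenes * n, lambda = mu), nGenes, n)
    }
    dimnames(counts) <- list(genes, samples)

    annotation <- data.frame(
      population = pop, batch = batch,
      subject = sprintf("subj%02d", seq_len(n)),
      tissue = ifelse(pop == groupLabels[1], "blood", "marrow"),
      row.names = samples, stringsAsFactors = FALSE)

    truth <- new("SyntheticTruth",
      plantedFactors = factors,
      plantedDeg = data.frame(gene = genes[de], lfc = lfc[de],
                              stringsAsFactors = FALSE),
      enrichedSets = character(0),
      batchAssignment = setNames(batch, samples),
      params = list(neighborDeProb = neighborDeProb,
                    backgroundDeProb = backgroundDeProb,
                    lfcScale = lfcScale, dispersion = dispersion,
                    batchEffectSd = batchEffectSd, nBatches = nBatches,
                    samplesPerGroup = samplesPerGroup,
                    groupLabels = groupLabels, seed = seed))
    list(study = CountStudy(counts, annotation), truth = truth)
  })
}

#' Construct a CountStudy from a count matrix and sample annotation
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param annotation data.frame with one row per sample; must contain a
#'   `population` column. Missing `batch`, `subject` or `tissue` columns are
#'   filled with placeholder levels.
#' @return a [CountStudy-class].
#' @export
CountStudy <- function(counts, annotation) {
  counts <- as.matrix(counts)
  annotation <- as.data.frame(annotation)
  if (nrow(annotation) != ncol(counts))
    stop("annotation must have one row per sample")
  if (is.null(rownames(annotation)) ||
      identical(rownames(annotation), as.character(seq_len(nrow(annotation))))) {
    if (!is.null(annotation$sample)) rownames(annotation) <- annotation$sample
    else rownames(annotation) <- colnames(counts)
  }
  if (!"population" %in% names(annotation))
    stop("annotation must contain a 'population' column")
  if (!"batch" %in% names(annotation)) annotation$batch <- "batch1"
  if (!"subject" %in% names(annotation))
    annotation$subject <- rownames(annotation)
  if (!"tissue" %in% names(annotation)) annotation$tissue <- "unspecified"
  annotation <- annotation[colnames(counts), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(annotation))
  new("CountStudy", se)
}
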