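#' Simulate a complete synthetic study
#'
#' Generates every input the pipeline consumes — PPI network, planted hub
#' factors, RNA-seq counts with planted differential expression, secretome
#' fraction proteomes, gene sets with planted enrichment, a target-decoy PSM
#' table and Elispot series — from a single integer seed. Module-level seeds
#' are derived deterministically from it, so the whole study is reproducible.
#'
#' @param seed integer master seed.
#' @param nNodes,nEdges,attachmentBias network parameters
#'   (see [generatePpiNetwork()]).
#' @param nFactors,minDegree planted factor parameters (see [plantFactors()]).
#' @param nGenes,samplesPerGroup,neighborDeProb,backgroundDeProb,lfcScale,dispersion,libSizeRange,batchEffectSd,nBatches
#'   count parameters (see [generateCounts()]).
#' @param nSets,setSizeRange,nEnriched,enrichmentFactor gene-set parameters
#'   (see [generateGeneSets()]).
#' @param dropoutRate,contaminantRate fraction-proteome parameters
#'   (see [generateFractionProteomes()]).
#' @param outdir optional directory; when given, all inputs are written as
#'   plain-text files (TSV/CSV/GMT/JSON).
#' @return list with `network`, `factors`, `study`, `truth`, `fractions`,
#'   `geneSets`, `psms`, `elispot`.
#' @export
simulateStudy <- function(seed = 1, nNodes = 500, nEdges = 2000,
                          attachmentBias = 1, nFactors = 5, minDegree = 15,
                          nGenes = 2000, samplesPerGroup = c(8, 4),
                          neighborDeProb = 0.5, backgroundDeProb = 0.05,
                          lfcScale = 1.5, dispersion = 0.1,
                          libSizeRange = c(5e5, 2e6), batchEffectSd = 1,
                          nBatches = 2, nSets = 25, setSizeRange = c(20, 80),
                          nEnriched = 5, enrichmentFactor = 5,
                          dropoutRate = 0, contaminantRate = 0.1,
                          outdir = NULL) {
  network <- generatePpiNetwork(nNodes, nEdges, attachmentBias,
                                seed = .subSeed(seed, 1))
  factors <- plantFactors(network, nFactors, minDegree,
                          seed = .subSeed(seed, 2))
  cs <- generateCounts(network, factors, nGenes = nGenes,
                       samplesPerGroup = samplesPerGroup,
                       neighborDeProb = neighborDeProb,
                       backgroundDeProb = backgroundDeProb,
                       lfcScale = lfcScale, dispersion = dispersion,
                       libSizeRange = libSizeRange,
                       batchEffectSd = batchEffectSd, nBatches = nBatches,
                       seed = .subSeed(seed, 3))
  gs <- generateGeneSets(rownames(countsMatrix(cs$study)), nSets = nSets,
                         sizeRange = setSizeRange, nEnriched = nEnriched,
                         truth = cs$truth, enrichmentFactor = enrichmentFactor,
                         seed = .subSeed(seed, 4))
  fractions <- generateFractionProteomes(factors,
                                         dropoutRate = dropoutRate,
                                         contaminantRate = contaminantRate,
                                         seed = .subSeed(seed, 5))
  psms <- generatePsmTable(seed = .subSeed(seed, 6))
  elispot <- generateElispotSeries(
    data.frame(name = c("media", "secretome"),
               day0Frac = c(1, 1), decayRate = c(0.6, 0.1)),
    seed = .subSeed(seed, 7))
  out <- list(network = network, factors = factors, study = cs$study,
              truth = gs$truth, fractions = fractions,
              geneSets = gs$collection, psms = psms, elispot = elispot)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeEdgeList(network, file.path(outdir, "network.tsv"))
    writeCountMatrix(countsMatrix(cs$study), file.path(outdir, "counts.tsv"))
    writeSampleAnnotation(sampleInfo(cs$study),
                          file.path(outdir, "annotation.tsv"))
    writeGmt(gs$collection, file.path(outdir, "gene_sets.gmt"))
    for (f in fractions)
      writeProteinList(fractionProteins(f),
                       file.path(outdir, paste0("fraction_", f@fractionId, ".csv")))
    writePsmTable(psms, file.path(outdir, "psms.tsv"))
    writeElispot(elispot, file.path(outdir, "elispot.csv"))
    writeTruth(gs$truth, file.path(outdir, "truth.json"))
  }
  out
}

.configDefaults <- function() list(
  seed = 1,
  thresholds = list(psm_fdr = 0.01, min_peptide_length = 7,
                    min_abundance_log2 = 3, deg_fdr = 0.05, gsea_fdr = 0.05,
                    report_threshold = 45, min_confidence = 0),
  n_perm = 1000,
  flags = list(adjust_batch = TRUE, include_seed_partners = TRUE,
               log_scale_survival = FALSE),
  groups = list(a = NULL, b = NULL),
  funnel = list(primary = NULL, control = NULL),
  paths = list())

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills in defaults, checks every
#' threshold range and (when `checkPaths = TRUE`) that every referenced path
#' resolves, and reports all violations at once.
#'
#' @param config YAML file path or list.
#' @param checkPaths verify that configured input paths exist.
#' @return validated config list of class `PipelineConfig`.
#' @export
validateConfig <- function(config, checkPaths = TRUE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- .configDefaults()
  merged <- utils::modifyList(def, config)
  errs <- character(0)
  th <- merged$thresholds
  chk <- function(name, lo, hi) {
    v <- th[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      errs <<- c(errs, sprintf("thresholds$%s must be a number in [%g, %g] (got %s)",
                               name, lo, hi, paste(v, collapse = ",")))
  }
  chk("psm_fdr", 0, 1); chk("deg_fdr", 0, 1); chk("gsea_fdr", 0, 1)
  chk("min_confidence", 0, 1)
  chk("min_peptide_length", 1, Inf); chk("min_abundance_log2", -Inf, Inf)
  chk("report_threshold", 0, Inf)
  if (!is.numeric(merged$n_perm) || merged$n_perm < 1)
    errs <- c(errs, "n_perm must be a positive integer")
  if (!is.numeric(merged$seed))
    errs <- c(errs, "seed must be an integer")
  if (checkPaths && length(merged$paths)) {
    for (nm in names(merged$paths)) {
      p <- merged$paths[[nm]]
      if (nm %in% c("outdir", "network_dialect")) next
      if (is.character(p) && length(p) == 1 && !file.exists(p))
        errs <- c(errs, sprintf("paths$%s does not resolve: %s", nm, p))
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(merged) <- c("PipelineConfig", class(merged))
  merged
}

#' Run the integrated prioritization pipeline end to end
#'
#' Executes, in order: the secretome funnel (bioactive union, background
#' subtraction, differential proteome, intersection), first-neighbor PPI
#' expansion of the resulting seeds, the differential-expression core,
#' the DEG/partner integration and candidate ranking, pre-ranked GSEA on the
#' contrast t-statistic, and eigengene summarization with Ward clustering of
#' the significant sets. Inputs come either from the paths in `config` or
#' from in-memory objects in `inputs` (which take precedence).
#'
#' @param config a `PipelineConfig` (see [validateConfig()]) or a list
#'   coercible to one.
#' @param inputs optional list with elements `network` ([PPINetwork-class]),
#'   `study` ([CountStudy-class]), `fractions` (list of
#'   [FractionProteome-class]), `geneSets` (named list) and optionally
#'   `psms`.
#' @return a pipeline report: list with `funnel` (a
#'   [ProteinSetReport-class]), `funnelCounts`, `expansion`, `deg`,
#'   `degGenes`, `overlapTargets`, `candidates`, `gsea`, `nSignificantSets`,
#'   `eigengenes`, `wardNewick`, `psmProteins`, `seed` and `config`. When
#'   `config$paths$outdir` is set, stage outputs are also serialized there.
#' @export
runPipeline <- function(config = list(), inputs = NULL) {
  if (!inherits(config, "PipelineConfig"))
    config <- validateConfig(config, checkPaths = is.null(inputs))
  th <- config$thresholds
  paths <- config$paths

  getInput <- function(name, loader) {
    if (!is.null(inputs[[name]])) return(inputs[[name]])
    if (!is.null(paths[[name]])) return(loader(paths[[name]]))
    stop("pipeline stage '", name, "' failed: no input provided (set paths$",
         name, " or inputs$", name, ")")
  }

  network <- getInput("network", function(p)
    loadNetwork(p, dialect = paths$network_dialect %||% "edgelist",
                minConfidence = th$min_confidence))
  study <- if (!is.null(inputs$study)) inputs$study else {
    counts <- getInput("counts", readCountMatrix)
    ann <- getInput("annotation", readSampleAnnotation)
    CountStudy(counts, ann)
  }
  geneSets <- getInput("geneSets", readGmt)
  fractions <- if (!is.null(inputs$fractions)) inputs$fractions else {
    if (is.null(paths$fractions))
      stop("pipeline stage 'fractions' failed: no fraction proteomes provided")
    lapply(paths$fractions, function(fr)
      new("FractionProteome", fractionId = fr$id, activity = fr$activity,
          proteins = normalizeIdentifiers(readProteinList(fr$path))))
  }

  psmProteins <- NULL
  psms <- if (!is.null(inputs$psms)) inputs$psms
          else if (!is.null(paths$psms)) readPsmTable(paths$psms) else NULL
  if (!is.null(psms))
    psmProteins <- filterPsms(psms, fdrThreshold = th$psm_fdr,
                              minLength = th$min_peptide_length)

  # --- secretome funnel -------------------------------------------------
  acts <- vapply(fractions, fractionActivity, character(1))
  actives <- fractions[acts == "bioactive"]
  inactives <- fractions[acts == "inactive"]
  backgroundFr <- fractions[acts == "background"]
  if (!length(actives)) stop("funnel failed: no bioactive fractions")
  background <- if (length(backgroundFr))
    fractionProteins(backgroundFr[[1]]) else character(0)
  primaryId <- config$funnel$primary %||% actives[[1]]@fractionId
  controlId <- config$funnel$control %||%
    (if (length(inactives)) inactives[[1]]@fractionId else NULL)
  byId <- setNames(fractions, vapply(fractions, function(f) f@fractionId,
                                     character(1)))
  ua <- unionActive(actives)
  uni <- subtractBackground(ua, background)
  attr(uni, "provenance") <- attr(ua, "provenance")[uni]
  diffSet <- if (!is.null(controlId)) {
    differentialProteome(
      subtractBackground(fractionProteins(byId[[primaryId]]), background),
      subtractBackground(fractionProteins(byId[[controlId]]), background))
  } else subtractBackground(fractionProteins(byId[[primaryId]]), background)
  funnel <- intersectExperiments(uni, diffSet)
  seeds <- funnel@intersection
  if (!length(seeds))
    warning("funnel produced an empty seed set; downstream stages will be empty")

  # --- PPI expansion ----------------------------------------------------
  expansion <- if (length(seeds))
    expandSeeds(network, seeds,
                includeSeedPartners = config$flags$include_seed_partners)
  else new("ExpansionResult", perSeed = list(), unmatchedSeeds = character(0))

  # --- differential expression -----------------------------------------
  degRun <- runDegAnalysis(study,
                           groupA = config$groups$a, groupB = config$groups$b,
                           minMeanLog2 = th$min_abundance_log2,
                           fdr = th$deg_fdr,
                           adjustBatch = isTRUE(config$flags$adjust_batch))
  degGenes <- callDegs(degRun$deg, th$deg_fdr)

  # --- integration ------------------------------------------------------
  targets <- if (length(perSeed(expansion)))
    overlapTargets(expansion, degGenes) else character(0)
  cand <- if (length(perSeed(expansion)))
    rankCandidates(expansion, degGenes,
                   reportThreshold = th$report_threshold)
  else new("CandidateTable",
           table = data.frame(seed = character(0),
                              n_partners_total = integer(0),
                              n_partners_deg = integer(0), rank = integer(0),
                              flagged = logical(0)),
           partnerDegSymbols = list(), reportThreshold = th$report_threshold)

  # --- enrichment -------------------------------------------------------
  tb <- degTable(degRun$deg)
  ranking <- setNames(tb$contrast_t, tb$gene)
  gsea <- gseaPreranked(ranking, geneSets, nPerm = config$n_perm,
                        seed = .subSeed(config$seed, 101))
  gt <- gseaTable(gsea)
  sig <- gt$pathway[!is.na(gt$q_value) & gt$q_value <= th$gsea_fdr]

  # --- eigengene summarization -----------------------------------------
  ann <- sampleInfo(study)
  slsm <- standardizeSlsm(degRun$expr, ann$population)
  eig <- NULL; newick <- NULL
  if (length(sig)) {
    prof <- lapply(setNames(sig, sig), function(nm) {
      members <- intersect(geneSets[[nm]], rownames(slsm))
      if (length(members)) genesetPc1(slsm, members)$scores else NULL
    })
    prof <- prof[!vapply(prof, is.null, logical(1))]
    if (length(prof)) {
      eig <- do.call(rbind, prof)
      if (nrow(eig) >= 2) newick <- wardCluster(eig)$newick
    }
  }

  report <- list(
    funnel = funnel,
    funnelCounts = c(union_active = length(funnel@unionActive),
                     differential = length(funnel@differential),
                     intersection = length(seeds),
                     union_partners = length(unionPartners(expansion)),
                     deg = length(degGenes),
                     overlap_targets = length(targets),
                     significant_sets = length(sig)),
    expansion = expansion,
    deg = degRun$deg,
    degGenes = degGenes,
    overlapTargets = targets,
    candidates = cand,
    gsea = gsea,
    nSignificantSets = length(sig),
    eigengenes = eig,
    wardNewick = newick,
    psmProteins = psmProteins,
    seed = config$seed,
    config = unclass(config)[c("seed", "thresholds", "n_perm", "flags",
                               "groups", "funnel")])

  outdir <- paths$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(candidates(cand), file.path(outdir, "candidates.csv"),
              row.names = FALSE)
    write.table(gseaTable(gsea), file.path(outdir, "gsea.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(degTable(degRun$deg), file.path(outdir, "deg.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(funnel_counts = as.list(report$funnelCounts),
           seed = config$seed,
           n_significant_sets = report$nSignificantSets,
           config = report$config),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(newick))
      writeLines(newick, file.path(outdir, "gsea_ward.nwk"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
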