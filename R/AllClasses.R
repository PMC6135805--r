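# Central S4 containers. Constructors live next to the operations that
# produce them; accessors and show() methods are defined here.

#' PPINetwork: an undirected weighted protein-protein interaction network
#'
#' Nodes are gene symbols; edges carry a confidence in \[0, 1\] and an optional
#' evidence string. The edge table is canonical: no self-loops, no duplicate
#' (unordered) pairs, `nodeA < nodeB` lexicographically, rows sorted.
#'
#' @slot nodes character vector of node symbols (sorted, unique).
#' @slot edges data.frame with columns `nodeA`, `nodeB`, `confidence`,
#'   `evidence`.
#' @export
setClass("PPINetwork",
  representation(nodes = "character", edges = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    e <- object@edges
    need <- c("nodeA", "nodeB", "confidence")
    if (!all(need %in% names(e)))
      return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
      if (any(e$nodeA == e$nodeB)) msg <- c(msg, "self-loops are not allowed")
      if (any(e$nodeA > e$nodeB)) msg <- c(msg, "edges must be canonical (nodeA < nodeB)")
      if (anyDuplicated(paste(e$nodeA, e$nodeB))) msg <- c(msg, "duplicate edges")
      if (any(e$confidence < 0 | e$confidence > 1)) msg <- c(msg, "confidence outside [0, 1]")
      if (!all(c(e$nodeA, e$nodeB) %in% object@nodes))
        msg <- c(msg, "edge endpoints missing from node set")
    }
    if (length(msg)) msg else TRUE
  })

#' CountStudy: RNA-seq counts with sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `counts` assay holds
#' non-negative integer gene-by-sample counts and whose `colData` carries the
#' study design (`population`, `batch`, `subject`, `tissue`).
#'
#' @export
setClass("CountStudy", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      return("a 'counts' assay is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    need <- c("population", "batch", "subject", "tissue")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
      msg <- c(msg, paste("annotation missing column(s):", paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' SyntheticTruth: the planted ground truth of a simulated study
#'
#' @slot plantedFactors gene symbols of the planted hub secretome factors.
#' @slot plantedDeg data.frame with columns `gene`, `lfc` (signed log2
#'   fold-change) for genes planted as differentially expressed.
#' @slot enrichedSets names of gene sets built to over-represent planted DE
#'   genes.
#' @slot batchAssignment named character, sample -> batch label.
#' @slot params list of generator parameters (probabilities, effect sizes).
#' @export
setClass("SyntheticTruth",
  representation(plantedFactors = "character", plantedDeg = "data.frame",
                 enrichedSets = "character", batchAssignment = "character",
                 params = "list"),
  validity = function(object) {
    msg <- character(0)
    p <- object@params
    for (nm in c("neighborDeProb", "backgroundDeProb"))
      if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1))
        msg <- c(msg, paste(nm, "outside [0, 1]"))
    if (nrow(object@plantedDeg) &&
        !all(c("gene", "lfc") %in% names(object@plantedDeg)))
      msg <- c(msg, "plantedDeg needs columns gene, lfc")
    if (length(msg)) msg else TRUE
  })

#' FractionProteome: proteins identified in one secretome fraction
#'
#' @slot fractionId fraction label.
#' @slot activity one of `"bioactive"`, `"inactive"`, `"background"`.
#' @slot proteins normalized protein/gene symbols (sorted, unique, uppercase).
#' @export
setClass("FractionProteome",
  representation(fractionId = "character", activity = "character",
                 proteins = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@activity %in% c("bioactive", "inactive", "background"))
      msg <- c(msg, "activity must be bioactive, inactive or background")
    if (anyDuplicated(object@proteins)) msg <- c(msg, "duplicate proteins")
    if (length(object@proteins) && any(object@proteins == ""))
      msg <- c(msg, "empty protein identifiers")
    if (length(msg)) msg else TRUE
  })

#' ProteinSetReport: provenance-tracked result of the secretome funnel
#'
#' @slot unionActive proteins in the union of bioactive fractions (background
#'   subtracted).
#' @slot differential proteins in the differential comparison (primary
#'   bioactive fraction minus the inactive control).
#' @slot intersection overlap of the two experiments; the candidate seed set.
#' @slot provenance named list, protein -> contributing fraction ids.
#' @export
setClass("ProteinSetReport",
  representation(unionActive = "character", differential = "character",
                 intersection = "character", provenance = "list"),
  validity = function(object) {
    msg <- character(0)
    if (!all(object@intersection %in% object@unionActive) ||
        !all(object@intersection %in% object@differential))
      msg <- c(msg, "intersection must be contained in both input sets")
    if (length(object@intersection) &&
        !all(object@intersection %in% names(object@provenance)))
      msg <- c(msg, "provenance must cover every retained protein")
    if (length(msg)) msg else TRUE
  })

#' ExpansionResult: first-neighbor expansion of seed proteins
#'
#' @slot perSeed named list, seed symbol -> character vector of partners.
#' @slot unmatchedSeeds seeds absent from the network.
#' @export
setClass("ExpansionResult",
  representation(perSeed = "list", unmatchedSeeds = "character"))

#' DEGResult: per-gene differential-expression statistics
#'
#' @slot table data.frame with columns `gene`, `mean_log2`, `F_statistic`,
#'   `contrast_t`, `p_value`, `q_value`, `is_deg`.
#' @slot fdr FDR threshold used for the `is_deg` flag.
#' @slot groups the two populations contrasted (`contrast_t` sign is
#'   `groups[1]` minus `groups[2]`).
#' @export
setClass("DEGResult",
  representation(table = "data.frame", fdr = "numeric", groups = "character"),
  validity = function(object) {
    need <- c("gene", "mean_log2", "F_statistic", "contrast_t",
              "p_value", "q_value", "is_deg")
    if (!all(need %in% names(object@table)))
      return(paste("table must have columns", paste(need, collapse = ", ")))
    tb <- object@table
    if (nrow(tb) && !identical(tb$is_deg, tb$q_value <= object@fdr))
      return("is_deg flag inconsistent with q_value and fdr")
    TRUE
  })

#' PcvaReport: variance of leading principal components attributed to design factors
#'
#' @slot contributions named numeric, percent of the variance-weighted first-k
#'   PC score variance attributed to each annotation factor (one-way R^2).
#' @slot residual percent left unattributed (100 minus the sum; can drift from
#'   a strict partition when factors are correlated).
#' @slot varianceExplained share of total expression variance carried by each
#'   of the first k PCs.
#' @slot perPc matrix of per-PC R^2 values (factor x PC).
#' @export
setClass("PcvaReport",
  representation(contributions = "numeric", residual = "numeric",
                 varianceExplained = "numeric", perPc = "matrix"),
  validity = function(object) {
    if (any(object@contributions < -1e-8)) "negative contribution" else TRUE
  })

#' CandidateTable: secretome proteins ranked by differentially expressed partners
#'
#' @slot table data.frame with columns `seed`, `n_partners_total`,
#'   `n_partners_deg`, `rank`, `flagged`.
#' @slot partnerDegSymbols named list, seed -> DEG-overlapping partner symbols.
#' @slot reportThreshold count above which a seed is flagged.
#' @export
setClass("CandidateTable",
  representation(table = "data.frame", partnerDegSymbols = "list",
                 reportThreshold = "numeric"),
  validity = function(object) {
    tb <- object@table
    msg <- character(0)
    if (nrow(tb)) {
      if (any(tb$n_partners_deg > tb$n_partners_total))
        msg <- c(msg, "n_partners_deg exceeds n_partners_total")
      if (!identical(sort(tb$rank), seq_len(nrow(tb))))
        msg <- c(msg, "ranks must be 1..n without gaps")
    }
    if (length(msg)) msg else TRUE
  })

#' GseaResult: pre-ranked gene-set enrichment results
#'
#' @slot table data.frame with columns `pathway`, `size`, `ES`, `NES`,
#'   `p_value`, `q_value`, `direction`.
#' @slot leadingEdges named list, pathway -> leading-edge genes (ranked order).
#' @slot nPerm number of gene-label permutations used for the null.
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("GseaResult",
  representation(table = "data.frame", leadingEdges = "list",
                 nPerm = "numeric", seed = "numeric"),
  validity = function(object) {
    tb <- object@table
    if (nrow(tb) && any(abs(tb$ES) > 1 + 1e-12)) "|ES| must be <= 1" else TRUE
  })

# ---- accessors ----------------------------------------------------------

#' @describeIn PPINetwork-class node symbols
#' @param x a `PPINetwork`
#' @export
ppiNodes <- function(x) x@nodes

#' @describeIn PPINetwork-class canonical edge table
#' @export
ppiEdges <- function(x) x@edges

#' @describeIn ExpansionResult-class per-seed first-neighbor sets
#' @param x an `ExpansionResult`
#' @export
perSeed <- function(x) x@perSeed

#' @describeIn ExpansionResult-class seeds not found in the network
#' @export
unmatchedSeeds <- function(x) x@unmatchedSeeds

#' @describeIn ExpansionResult-class union of all partner sets
#' @export
unionPartners <- function(x) .asSet(unlist(x@perSeed, use.names = FALSE))

#' @describeIn DEGResult-class the per-gene statistics table
#' @param x a `DEGResult`
#' @export
degTable <- function(x) x@table

#' @describeIn CandidateTable-class the ranked candidate table
#' @param x a `CandidateTable`
#' @export
candidates <- function(x) x@table

#' @describeIn GseaResult-class the per-set enrichment table
#' @param x a `GseaResult`
#' @export
gseaTable <- function(x) x@table

#' @describeIn GseaResult-class leading-edge genes per set
#' @export
leadingEdges <- function(x) x@leadingEdges

#' @describeIn CountStudy-class counts assay as a plain matrix
#' @param x a `CountStudy`
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn CountStudy-class sample annotation as a data.frame
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn SyntheticTruth-class planted hub factor symbols
#' @param x a `SyntheticTruth`
#' @export
plantedFactors <- function(x) x@plantedFactors

#' @describeIn SyntheticTruth-class planted DE genes with signed log2 fold-changes
#' @export
plantedDeg <- function(x) x@plantedDeg

#' @describeIn SyntheticTruth-class names of the planted enriched gene sets
#' @export
enrichedSets <- function(x) x@enrichedSets

#' @describeIn FractionProteome-class protein symbols of the fraction
#' @param x a `FractionProteome`
#' @export
fractionProteins <- function(x) x@proteins

#' @describeIn FractionProteome-class activity label of the fraction
#' @export
fractionActivity <- function(x) x@activity

# ---- show methods -------------------------------------------------------

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  confidence range:",
        sprintf("[%.3f, %.3f]", min(object@edges$confidence),
                max(object@edges$confidence)), "\n")
})

setMethod("show", "ExpansionResult", function(object) {
  cat("ExpansionResult:", length(object@perSeed), "matched seed(s),",
      length(unionPartners(object)), "distinct partner(s),",
      length(object@unmatchedSeeds), "unmatched seed(s)\n")
})

setMethod("show", "DEGResult", function(object) {
  tb <- object@table
  cat("DEGResult:", nrow(tb), "genes tested,", sum(tb$is_deg),
      sprintf("differentially expressed at FDR <= %g", object@fdr), "\n")
  cat("  contrast:", paste(object@groups, collapse = " vs "), "\n")
})

setMethod("show", "CandidateTable", function(object) {
  cat("CandidateTable:", nrow(object@table), "candidate(s); top rows:\n")
  print(utils::head(object@table, 5))
})

setMethod("show", "GseaResult", function(object) {
  tb <- object@table
  cat("GseaResult:", nrow(tb), "sets tested,", sum(tb$q_value <= 0.05, na.rm = TRUE),
      "at q <= 0.05 (", object@nPerm, "permutations )\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@plantedFactors), "planted factor(s),",
      nrow(object@plantedDeg), "planted DE gene(s),",
      length(object@enrichedSets), "enriched set(s)\n")
})

setMethod("show", "FractionProteome", function(object) {
  cat(sprintf("FractionProteome '%s' (%s): %d proteins\n",
              object@fractionId, object@activity, length(object@proteins)))
})

setMethod("show", "ProteinSetReport", function(object) {
  cat("ProteinSetReport: |union_active| =", length(object@unionActive),
      ", |differential| =", length(object@differential),
      ", |intersection| =", length(object@intersection), "\n")
})

setMethod("show", "PcvaReport", function(object) {
  cat("PcvaReport (percent of weighted PC variance):\n")
  print(round(object@contributions, 2))
  cat("  residual:", round(object@residual, 2), "\n")
})
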