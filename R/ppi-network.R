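#' Construct a PPINetwork from an edge table
#'
#' Canonicalizes the edge list: orders each pair lexicographically, drops
#' self-loops (with a warning), merges duplicate edges keeping the maximum
#' confidence, and sorts rows.
#'
#' @param edges data.frame with columns `nodeA`, `nodeB`, `confidence` and
#'   optionally `evidence`.
#' @param nodes optional full node set (to keep isolated nodes); defaults to
#'   the endpoints present in `edges`.
#' @return a [PPINetwork-class].
#' @export
PPINetwork <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (!"evidence" %in% names(edges)) edges$evidence <- ""
  edges$nodeA <- as.character(edges$nodeA)
  edges$nodeB <- as.character(edges$nodeB)
  loop <- edges$nodeA == edges$nodeB
  if (any(loop)) {
    warning("dropped ", sum(loop), " self-loop(s)")
    edges <- edges[!loop, , drop = FALSE]
  }
  if (nrow(edges)) {
    swap <- edges$nodeA > edges$nodeB
    tmp <- edges$nodeA[swap]
    edges$nodeA[swap] <- edges$nodeB[swap]
    edges$nodeB[swap] <- tmp
    key <- paste(edges$nodeA, edges$nodeB, sep = "\r")
    if (anyDuplicated(key)) {
      best <- tapply(seq_len(nrow(edges)), key,
                     function(ix) ix[which.max(edges$confidence[ix])])
      edges <- edges[sort(unlist(best)), , drop = FALSE]
    }
    edges <- edges[order(edges$nodeA, edges$nodeB), , drop = FALSE]
  }
  rownames(edges) <- NULL
  allNodes <- .asSet(c(nodes, edges$nodeA, edges$nodeB))
  new("PPINetwork", nodes = allNodes,
      edges = edges[, c("nodeA", "nodeB", "confidence", "evidence")])
}

#' Load a PPI network from a HIPPIE-style or generic edge-list file
#'
#' The `hippie` dialect expects tab-separated rows
#' `entryNameA <tab> entrezA <tab> entryNameB <tab> entrezB <tab> confidence
#' <tab> evidence`; the `edgelist` dialect expects
#' `nodeA <tab> nodeB <tab> confidence [<tab> evidence]` with an optional
#' header. Identifiers are uppercased and mapped through `mapping` when
#' given; unmapped ids keep their raw (uppercased) name and are flagged.
#' Edges below `minConfidence` and self-loops are dropped; duplicate edges
#' keep the maximum confidence.
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"hippie"`.
#' @param minConfidence minimum confidence retained (inclusive).
#' @param mapping optional named character vector raw id -> gene symbol.
#' @return a [PPINetwork-class].
#' @export
loadNetwork <- function(path, dialect = c("edgelist", "hippie"),
                        minConfidence = 0, mapping = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  confCol <- if (dialect == "hippie") 5L else 3L
  nodeCols <- if (dialect == "hippie") c(1L, 3L) else c(1L, 2L)
  # tolerate a single header line (non-numeric confidence field)
  if (length(fields[[1]]) >= confCol &&
      is.na(suppressWarnings(as.numeric(fields[[1]][confCol])))) start <- 2L
  if (start > length(fields)) stop("empty network file: ", path)
  rows <- lapply(seq(start, length(fields)), function(i) {
    f <- fields[[i]]
    if (length(f) < confCol)
      stop("malformed row at line ", i, " of ", path,
           ": expected at least ", confCol, " fields")
    conf <- suppressWarnings(as.numeric(f[confCol]))
    if (is.na(conf))
      stop("malformed row at line ", i, " of ", path,
           ": non-numeric confidence '", f[confCol], "'")
    evidence <- if (length(f) > confCol) f[confCol + 1L] else ""
    c(f[nodeCols[1]], f[nodeCols[2]], conf, evidence)
  })
  m <- do.call(rbind, rows)
  edges <- data.frame(nodeA = toupper(m[, 1]), nodeB = toupper(m[, 2]),
                      confidence = as.numeric(m[, 3]), evidence = m[, 4],
                      stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    names(mapping) <- toupper(names(mapping))
    for (col in c("nodeA", "nodeB")) {
      hit <- edges[[col]] %in% names(mapping)
      edges[[col]][hit] <- toupper(unname(mapping[edges[[col]][hit]]))
    }
    unmapped <- .asSet(c(edges$nodeA, edges$nodeB)[
      !c(edges$nodeA, edges$nodeB) %in% toupper(unname(mapping))])
    if (length(unmapped))
      message(length(unmapped), " node id(s) had no mapping entry and keep their raw name")
  }
  low <- edges$confidence < minConfidence
  if (any(low)) {
    message("dropped ", sum(low), " edge(s) below confidence ", minConfidence)
    edges <- edges[!low, , drop = FALSE]
  }
  PPINetwork(edges)
}

# adjacency list (named list node -> neighbor symbols) via igraph
.adjacency <- function(network) {
  e <- ppiEdges(network)
  g <- igraph::graph_from_data_frame(e[, c("nodeA", "nodeB")],
                                     directed = FALSE,
                                     vertices = ppiNodes(network))
  adj <- igraph::as_adj_list(g)
  lapply(adj, function(vs) sort(names(vs)))
}

#' Expand seed proteins to their first interaction neighbors
#'
#' @param network a [PPINetwork-class].
#' @param seeds character vector of seed symbols (non-empty).
#' @param includeSeedPartners when `FALSE`, other seeds are removed from each
#'   partner set.
#' @return an [ExpansionResult-class]; seeds absent from the network appear
#'   in `unmatchedSeeds` and get no partner set.
#' @export
expandSeeds <- function(network, seeds, includeSeedPartners = TRUE) {
  seeds <- .asSet(seeds)
  if (!length(seeds)) stop("empty seed set")
  nodes <- ppiNodes(network)
  unmatched <- setdiff(seeds, nodes)
  matched <- intersect(seeds, nodes)
  adj <- .adjacency(network)
  per <- lapply(setNames(matched, matched), function(s) {
    nb <- adj[[s]]
    if (!includeSeedPartners) nb <- setdiff(nb, seeds)
    nb
  })
  new("ExpansionResult", perSeed = per, unmatchedSeeds = unmatched)
}

#' Per-node degree table
#'
#' @param network a [PPINetwork-class].
#' @return data.frame with columns `symbol`, `degree`, ordered by decreasing
#'   degree then symbol.
#' @export
degreeSummary <- function(network) {
  e <- ppiEdges(network)
  nodes <- ppiNodes(network)
  deg <- table(factor(c(e$nodeA, e$nodeB), levels = nodes))
  out <- data.frame(symbol = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
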