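#' Generate a sparse weighted PPI network with hub structure
#'
#' Builds a simple undirected graph over synthetic gene symbols
#' (`G000001 ...`): a random spanning chain keeps the graph essentially
#' connected, and the remaining edges attach preferentially to high-degree
#' nodes with weight `(degree + 1)^attachmentBias`, producing the right-skewed
#' degree distribution typical of curated interactomes. Edge confidences are
#' drawn uniform on \[0.5, 1\].
#'
#' @param nNodes number of nodes (>= 2).
#' @param nEdges number of edges; must be in `[nNodes - 1, nNodes(nNodes-1)/2]`.
#' @param attachmentBias preferential-attachment exponent; 0 gives a uniform
#'   random graph, larger values stronger hubs.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [PPINetwork-class].
#' @examples
#' net <- generatePpiNetwork(50, 120, seed = 1)
#' net
#' @export
generatePpiNetwork <- function(nNodes, nEdges, attachmentBias = 1, seed = 1) {
  if (nNodes < 2) stop("nNodes must be at least 2")
  maxEdges <- nNodes * (nNodes - 1) / 2
  if (nEdges > maxEdges)
    stop("invalid parameter: nEdges (", nEdges, ") exceeds the maximum ",
         maxEdges, " for ", nNodes, " nodes")
  if (nEdges < nNodes - 1)
    stop("nEdges must be at least nNodes - 1 (spanning chain)")
  withr::with_seed(seed, {
    nodes <- sprintf("G%06d", seq_len(nNodes))
    perm <- sample.int(nNodes)
    a <- perm[-nNodes]
    b <- perm[-1]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    have <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(a)) assign(paste(a[i], b[i]), TRUE, envir = have)
    deg <- tabulate(c(a, b), nNodes)
    m <- nNodes - 1
    rejects <- 0L
    while (m < nEdges) {
      w <- (deg + 1)^attachmentBias
      i <- sample.int(nNodes, 1, prob = w)
      j <- sample.int(nNodes, 1, prob = w)
      lo <- min(i, j); hi <- max(i, j)
      key <- paste(lo, hi)
      if (i == j || exists(key, envir = have, inherits = FALSE)) {
        rejects <- rejects + 1L
        # dense graphs: fall back to enumerating the missing pairs
        if (rejects > 200L) {
          all <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
          keys <- paste(all[, 1], all[, 2])
          free <- !vapply(keys, exists, logical(1), envir = have, inherits = FALSE)
          idx <- which(free)
          need <- nEdges - m
          pick <- idx[sample.int(length(idx), need,
                                 prob = ((deg[all[idx, 1]] + 1) *
                                         (deg[all[idx, 2]] + 1))^attachmentBias)]
          for (p in pick) {
            a <- c(a, all[p, 1]); b <- c(b, all[p, 2])
            deg[all[p, 1]] <- deg[all[p, 1]] + 1L
            deg[all[p, 2]] <- deg[all[p, 2]] + 1L
          }
          m <- nEdges
          break
        }
        next
      }
      rejects <- 0L
      assign(key, TRUE, envir = have)
      a <- c(a, lo); b <- c(b, hi)
      deg[lo] <- deg[lo] + 1L
      deg[hi] <- deg[hi] + 1L
      m <- m + 1L
    }
    conf <- runif(nEdges, 0.5, 1.0)
    edges <- data.frame(nodeA = nodes[a], nodeB = nodes[b],
                        confidence = conf, evidence = "synthetic",
                        stringsAsFactors = FALSE)
    PPINetwork(edges, nodes = nodes)
  })
}

#' Plant hub factors in a network
#'
#' Selects `nFactors` distinct nodes of degree at least `minDegree` uniformly
#' at random; these play the role of the abundant secretome proteins whose
#' interaction neighborhoods carry the differential-expression signal.
#'
#' @param network a [PPINetwork-class].
#' @param nFactors number of factors to plant.
#' @param minDegree minimum degree a factor node must have.
#' @param seed integer seed.
#' @return character vector of factor node symbols.
#' @export
plantFactors <- function(network, nFactors = 5, minDegree = 15, seed = 1) {
  ds <- degreeSummary(network)
  eligible <- ds$symbol[ds$degree >= minDegree]
  if (length(eligible) < nFactors) {
    achievable <- if (nrow(ds) >= nFactors) ds$degree[nFactors] else 0L
    stop("infeasible: only ", length(eligible), " node(s) have degree >= ",
         minDegree, "; the maximum achievable minDegree for ", nFactors,
         " factors is ", achievable)
  }
  withr::with_seed(seed, sort(sample(eligible, nFactors)))
}
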