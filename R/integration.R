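#' Overlap expanded interaction partners with the DEG set
#'
#' @param expansion an [ExpansionResult-class].
#' @param degs character vector of differentially expressed gene symbols.
#' @return sorted character vector: union of all partner sets intersected
#'   with `degs`.
#' @export
overlapTargets <- function(expansion, degs) {
  .asSet(intersect(unionPartners(expansion), .asSet(degs)))
}

#' Rank seed proteins by differentially expressed interaction partners
#'
#' For every seed, counts its total first-neighbor partners and the subset
#' that is differentially expressed, then sorts descending by DEG-overlapping
#' partners, breaking ties by total partners and finally by seed symbol.
#' Seeds whose DEG-overlap exceeds `reportThreshold` are flagged (a reporting
#' aid, not a filter).
#'
#' @param expansion an [ExpansionResult-class] (non-empty).
#' @param degs character vector of DEG symbols.
#' @param reportThreshold flagging threshold on `n_partners_deg`.
#' @return a [CandidateTable-class].
#' @export
rankCandidates <- function(expansion, degs, reportThreshold = 45) {
  per <- perSeed(expansion)
  if (!length(per)) stop("empty expansion: no matched seeds to rank")
  degs <- .asSet(degs)
  seeds <- names(per)
  nTotal <- vapply(per, length, integer(1))
  degSym <- lapply(per, function(p) intersect(p, degs))
  nDeg <- vapply(degSym, length, integer(1))
  ord <- order(-nDeg, -nTotal, seeds)
  tb <- data.frame(seed = seeds[ord],
                   n_partners_total = unname(nTotal[ord]),
                   n_partners_deg = unname(nDeg[ord]),
                   rank = seq_along(ord),
                   flagged = unname(nDeg[ord]) > reportThreshold,
                   row.names = NULL, stringsAsFactors = FALSE)
  new("CandidateTable", table = tb, partnerDegSymbols = degSym[ord],
      reportThreshold = reportThreshold)
}

#' Shared interaction partners of two seed proteins
#'
#' @param expansion an [ExpansionResult-class].
#' @param seedA,seedB seed symbols present in the expansion.
#' @param degs character vector of DEG symbols (may be empty).
#' @return list with `shared` (partners common to both seeds) and
#'   `sharedDeg` (the differentially expressed subset).
#' @export
pairwiseShared <- function(expansion, seedA, seedB, degs = character(0)) {
  per <- perSeed(expansion)
  for (s in c(seedA, seedB))
    if (!s %in% names(per)) stop("seed '", s, "' not in expansion")
  shared <- .asSet(intersect(per[[seedA]], per[[seedB]]))
  list(shared = shared, sharedDeg = .asSet(intersect(shared, .asSet(degs))))
}
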