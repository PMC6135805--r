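#' Pre-ranked gene-set enrichment with permutation FDR
#'
#' Genes are sorted by score (descending, ties broken by symbol). For each
#' set, the running-sum statistic increments at member genes by
#' `|score|^weightExponent` (normalized to sum 1 within the set) and
#' decrements at non-members by `1/(N - |S|)`; the enrichment score ES is the
#' signed maximum deviation. The null is built by gene-label permutation
#' (`nPerm` draws per set from one seeded stream); NES divides ES by the mean
#' magnitude of same-sign null ES values, the nominal p-value is the
#' same-sign null exceedance fraction, and FDR q pools null and observed NES
#' in the standard two-sided procedure. The leading edge contains the set
#' members up to the ES extremum.
#'
#' @param ranking named numeric vector, gene symbol -> ranking score (e.g.
#'   the contrast t-statistic).
#' @param sets named list of member character vectors (e.g. from
#'   [readGmt()]).
#' @param weightExponent hit-weight exponent; 0 gives the unweighted
#'   Kolmogorov-Smirnov form.
#' @param nPerm number of permutations (values below 100 warn: unstable FDR).
#' @param minSize,maxSize set-size bounds after restriction to the ranked
#'   universe.
#' @param seed integer seed for the permutation stream.
#' @return a [GseaResult-class].
#' @export
gseaPreranked <- function(ranking, sets, weightExponent = 1.0, nPerm = 1000,
                          minSize = 5, maxSize = 500, seed = 1) {
  if (is.null(names(ranking))) stop("ranking must be a named vector")
  if (nPerm < 100) warning("nPerm < 100: FDR estimates will be unstable")
  ord <- order(-ranking, names(ranking))
  scores <- as.numeric(ranking[ord])
  genes <- names(ranking)[ord]
  N <- length(genes)
  pos <- setNames(seq_len(N), genes)

  keep <- character(0)
  hitPos <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (!length(members)) {
      warning("set '", nm, "' has no members in the ranked universe; skipped")
      next
    }
    if (length(members) < minSize || length(members) > maxSize) next
    keep <- c(keep, nm)
    hitPos[[nm]] <- sort(unname(pos[members]))
  }
  if (!length(keep))
    return(new("GseaResult",
               table = data.frame(pathway = character(0), size = integer(0),
                                  ES = numeric(0), NES = numeric(0),
                                  p_value = numeric(0), q_value = numeric(0),
                                  direction = character(0)),
               leadingEdges = list(), nPerm = nPerm, seed = seed))

  absW <- abs(scores)^weightExponent
  obs <- vapply(keep, function(nm)
    .gseaEs(hitPos[[nm]], absW[hitPos[[nm]]], N), numeric(1))

  nullEs <- withr::with_seed(seed, {
    lapply(keep, function(nm) {
      k <- length(hitPos[[nm]])
      vapply(seq_len(nPerm), function(b) {
        p <- sort.int(sample.int(N, k))
        .gseaEs(p, absW[p], N)
      }, numeric(1))
    })
  })
  names(nullEs) <- keep

  nes <- pval <- rep(NA_real_, length(keep))
  nullNes <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ne <- nullEs[[i]]
    mpos <- mean(ne[ne > 0])
    mneg <- mean(abs(ne[ne < 0]))
    e <- obs[i]
    if (e >= 0) {
      nes[i] <- if (is.finite(mpos)) e / mpos else NA_real_
      pval[i] <- (1 + sum(ne >= e)) / (1 + sum(ne >= 0))
    } else {
      nes[i] <- if (is.finite(mneg)) e / mneg else NA_real_
      pval[i] <- (1 + sum(ne <= e)) / (1 + sum(ne < 0))
    }
    nn <- ne
    nn[ne > 0] <- if (is.finite(mpos)) ne[ne > 0] / mpos else NA_real_
    nn[ne < 0] <- if (is.finite(mneg)) ne[ne < 0] / mneg else NA_real_
    nullNes[[i]] <- nn
  }
  pool <- unlist(nullNes)
  pool <- pool[is.finite(pool)]
  q <- vapply(seq_along(keep), function(i) {
    s <- nes[i]
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      top <- sum(pool >= s) / max(1, sum(pool >= 0))
      bot <- sum(nes >= s, na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      top <- sum(pool <= s) / max(1, sum(pool < 0))
      bot <- sum(nes <= s, na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, top / max(bot, .Machine$double.eps))
  }, numeric(1))

  le <- lapply(seq_along(keep), function(i) {
    hp <- hitPos[[keep[i]]]
    w <- absW[hp]
    ext <- .gseaExtremum(hp, w, N, obs[i])
    if (obs[i] >= 0) genes[hp[hp <= ext]] else genes[hp[hp >= ext]]
  })
  names(le) <- keep

  tb <- data.frame(pathway = keep,
                   size = vapply(hitPos[keep], length, integer(1)),
                   ES = unname(obs), NES = nes, p_value = pval, q_value = q,
                   direction = ifelse(obs >= 0, "high", "low"),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("GseaResult", table = tb, leadingEdges = le, nPerm = nPerm, seed = seed)
}

# enrichment score: signed maximum deviation of the running sum.
# hitPos sorted positions, hitW their (unnormalized) weights, N list length.
.gseaEs <- function(hitPos, hitW, N) {
  k <- length(hitPos)
  if (k >= N) return(1)
  m <- 1 / (N - k)
  sw <- sum(hitW)
  w <- if (sw > 0) hitW / sw else rep(1 / k, k)
  cw <- cumsum(w)
  peaks <- cw - (hitPos - seq_len(k)) * m   # just after each hit
  troughs <- peaks - w                      # just before each hit
  maxDev <- max(peaks)
  minDev <- min(troughs)
  # ties favor the positive sign, with a tolerance so exact rational ties
  # are not decided by floating-point accumulation order
  if (maxDev >= -minDev - 1e-9) maxDev else minDev
}

# ranked-list position of the ES extremum (for the leading edge)
.gseaExtremum <- function(hitPos, hitW, N, es) {
  k <- length(hitPos)
  m <- 1 / (N - k)
  sw <- sum(hitW)
  w <- if (sw > 0) hitW / sw else rep(1 / k, k)
  cw <- cumsum(w)
  peaks <- cw - (hitPos - seq_len(k)) * m
  troughs <- peaks - w
  if (es >= 0) hitPos[which.max(peaks)] else hitPos[which.min(troughs)]
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the realized overlap between
#' a query and a target set drawn from a common universe, plus the fold
#' enrichment over expectation.
#'
#' @param query,target,universe character vectors of gene symbols; query and
#'   target are restricted to the universe.
#' @return list with `overlap`, `expected`, `foldEnrichment`, `p_value`.
#' @export
hypergeometricOverlap <- function(query, target, universe) {
  universe <- .asSet(universe)
  query <- intersect(.asSet(query), universe)
  target <- intersect(.asSet(target), universe)
  k <- length(intersect(query, target))
  U <- length(universe); Q <- length(query); Tn <- length(target)
  expected <- Q * Tn / U
  p <- phyper(k - 1, Tn, U - Tn, Q, lower.tail = FALSE)
  list(overlap = k, expected = expected,
       foldEnrichment = if (expected > 0) k / expected else NA_real_,
       p_value = p)
}
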