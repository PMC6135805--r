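#' Simulate secretome fraction proteomes around planted factors
#'
#' Every bioactive fraction contains the shared background proteome (the serum
#' analogue, present in all fractions) plus each planted factor with
#' probability `1 - dropoutRate`. Inactive fractions contain the background
#' plus spurious contaminants but never the factors. One extra fraction
#' labeled `background` carries the background alone, so subtracting it from
#' the bioactive union isolates the factors.
#'
#' @param factors planted factor symbols.
#' @param backgroundSize number of shared background proteins.
#' @param activeLabels,inactiveLabels fraction ids; must be disjoint.
#' @param dropoutRate per-fraction probability that a factor is missed.
#' @param contaminantRate per-fraction inclusion probability for each protein
#'   of the contaminant pool (pool size = `backgroundSize`).
#' @param seed integer seed.
#' @return list of [FractionProteome-class] objects (actives, inactives, then
#'   the background fraction `"fbs"`).
#' @export
generateFractionProteomes <- function(factors, backgroundSize = 150,
    activeLabels = c("secretome_irr", "secretome_nonirr", "supernatant_irr"),
    inactiveLabels = c("supernatant_nonirr", "sbac"),
    dropoutRate = 0, contaminantRate = 0.1, seed = 3) {
  if (length(intersect(activeLabels, inactiveLabels)))
    stop("active and inactive labels must be disjoint")
  for (p in c(dropoutRate, contaminantRate))
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]")
  withr::with_seed(seed, {
    background <- sprintf("FBS%04d", seq_len(backgroundSize))
    contamPool <- sprintf("CONT%04d", seq_len(backgroundSize))
    out <- list()
    for (id in activeLabels) {
      kept <- factors[runif(length(factors)) >= dropoutRate]
      out[[id]] <- new("FractionProteome", fractionId = id,
                       activity = "bioactive",
                       proteins = .asSet(c(background, kept)))
    }
    for (id in inactiveLabels) {
      contam <- contamPool[runif(length(contamPool)) < contaminantRate]
      out[[id]] <- new("FractionProteome", fractionId = id,
                       activity = "inactive",
                       proteins = .asSet(c(background, contam)))
    }
    out[["fbs"]] <- new("FractionProteome", fractionId = "fbs",
                        activity = "background",
                        proteins = .asSet(background))
    out
  })
}

#' Simulate a target-decoy peptide-spectrum-match table
#'
#' Decoy and null-target scores share one normal distribution; true-target
#' scores are shifted upward by `trueScoreMean - nullScoreMean`. Peptide
#' lengths are sampled from 6-30 amino acids so the minimum-length filter is
#' exercised. The hidden truth label is kept in the `is_true` column, which
#' [filterPsms()] never reads.
#'
#' @param nTrue,nNullTargets,nDecoys row counts per class.
#' @param trueScoreMean,nullScoreMean,scoreSd normal score parameters.
#' @param lengthRange integer pair of peptide lengths to sample from.
#' @param seed integer seed.
#' @return data.frame with columns `peptide`, `protein`, `length`, `score`,
#'   `is_decoy`, `is_true`.
#' @export
generatePsmTable <- function(nTrue = 1000, nNullTargets = 1000, nDecoys = 1000,
                             trueScoreMean = 3, nullScoreMean = 0,
                             scoreSd = 1, lengthRange = c(6, 30), seed = 5) {
  withr::with_seed(seed, {
    n <- nTrue + nNullTargets + nDecoys
    cls <- rep(c("true", "null", "decoy"), c(nTrue, nNullTargets, nDecoys))
    score <- c(rnorm(nTrue, trueScoreMean, scoreSd),
               rnorm(nNullTargets, nullScoreMean, scoreSd),
               rnorm(nDecoys, nullScoreMean, scoreSd))
    protein <- c(if (nTrue) sprintf("TPROT%04d", (seq_len(nTrue) - 1) %/% 3 + 1),
                 if (nNullTargets) sprintf("NPROT%04d", (seq_len(nNullTargets) - 1) %/% 3 + 1),
                 if (nDecoys) sprintf("DECOY%04d", (seq_len(nDecoys) - 1) %/% 3 + 1))
    data.frame(peptide = sprintf("PEP%06d", seq_len(n)),
               protein = protein,
               length = sample(seq(lengthRange[1], lengthRange[2]), n,
                               replace = TRUE),
               score = score,
               is_decoy = cls == "decoy",
               is_true = cls == "true",
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' `nEnriched` sets over-represent planted DE genes: each draws
#' `size * min(1, deFraction * enrichmentFactor)` members from the planted DE
#' genes of one randomly chosen fold-change direction (capped by
#' availability), the rest uniformly from the remaining universe. Remaining
#' sets sample uniformly. Enriched set names are recorded in the returned
#' truth object.
#'
#' @param universe gene symbols to draw from.
#' @param nSets total number of sets.
#' @param sizeRange integer pair of set sizes (inclusive).
#' @param nEnriched how many sets carry planted enrichment.
#' @param truth a [SyntheticTruth-class] (supplies the planted DE genes).
#' @param enrichmentFactor multiplier on the DE fraction inside enriched sets.
#' @param seed integer seed.
#' @return list with `collection` (named list of member vectors) and `truth`
#'   (input truth with `enrichedSets` filled in).
#' @export
generateGeneSets <- function(universe, nSets = 25, sizeRange = c(20, 80),
                             nEnriched = 5, truth, enrichmentFactor = 5,
                             seed = 9) {
  if (nEnriched > nSets) stop("nEnriched cannot exceed nSets")
  deg <- plantedDeg(truth)
  deFrac <- nrow(deg) / length(universe)
  withr::with_seed(seed, {
    sets <- vector("list", nSets)
    names(sets) <- sprintf("PATH%02d", seq_len(nSets))
    enrichedNames <- names(sets)[seq_len(nEnriched)]
    for (i in seq_len(nSets)) {
      size <- if (sizeRange[1] == sizeRange[2]) sizeRange[1]
              else sample(seq(sizeRange[1], sizeRange[2]), 1)
      if (i <= nEnriched && nrow(deg)) {
        dir <- sample(c(-1, 1), 1)
        pool <- deg$gene[sign(deg$lfc) == dir]
        nDe <- min(round(size * min(1, deFrac * enrichmentFactor)),
                   length(pool), size)
        members <- sample(pool, nDe)
        # remainder from non-DE genes, so the DE content is exactly nDe
        rest <- setdiff(universe, deg$gene)
        members <- c(members, sample(rest, size - nDe))
      } else {
        members <- sample(universe, size)
      }
      sets[[i]] <- sort(members)
    }
    truth@enrichedSets <- enrichedNames
    list(collection = sets, truth = truth)
  })
}

#' Simulate Elispot time courses with exponential decay
#'
#' Per-well spot counts are Poisson with mean
#' `maxSpots * day0Frac * exp(-decayRate * day)`.
#'
#' @param conditions data.frame with columns `name`, `day0Frac`, `decayRate`
#'   (per day).
#' @param days integer days assayed.
#' @param wellsPerDay replicate wells per day.
#' @param maxSpots expected spots at day 0 for `day0Frac = 1`.
#' @param seed integer seed.
#' @return named list (one element per condition) of data.frames with columns
#'   `condition`, `day`, `well`, `spots`.
#' @export
generateElispotSeries <- function(conditions, days = c(1, 2, 3, 5, 7, 14),
                                  wellsPerDay = 6, maxSpots = 100, seed = 13) {
  conditions <- as.data.frame(conditions)
  stopifnot(all(c("name", "day0Frac", "decayRate") %in% names(conditions)))
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(conditions))) {
      d <- rep(days, each = wellsPerDay)
      decay <- exp(-conditions$decayRate[i] * d)
      decay[d == 0] <- 1   # guards decayRate = Inf at day 0
      lam <- maxSpots * conditions$day0Frac[i] * decay
      out[[conditions$name[i]]] <- data.frame(
        condition = conditions$name[i],
        day = rep(days, each = wellsPerDay),
        well = rep(seq_len(wellsPerDay), length(days)),
        spots = rpois(length(lam), lam),
        stringsAsFactors = FALSE)
    }
    out
  })
}
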