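#' Target-decoy FDR filtering of peptide-spectrum matches
#'
#' Removes peptides shorter than `minLength`, estimates peptide-level
#' q-values by the concatenated target-decoy method, aggregates retained
#' target peptides to proteins by best peptide score, and applies the same
#' target-decoy q-value procedure at the protein level with the same
#' threshold. At each score threshold s the false-discovery proportion is
#' estimated as `#(decoys >= s) / #(targets >= s)` (or `(#decoys + 1) /
#' #targets` when `conservative = TRUE`); the q-value of a match is the
#' minimum estimate over all thresholds that admit it. Decoys sort before
#' targets at tied scores.
#'
#' @param psms data.frame with columns `peptide`, `protein`, `length`,
#'   `score`, `is_decoy`.
#' @param fdrThreshold q-value threshold applied at both levels.
#' @param minLength minimum peptide length retained.
#' @param conservative use the `(#decoys + 1)/#targets` estimator.
#' @return sorted character vector of target proteins passing both filters.
#' @export
filterPsms <- function(psms, fdrThreshold = 0.01, minLength = 7,
                       conservative = FALSE) {
  need <- c("peptide", "protein", "length", "score", "is_decoy")
  if (!all(need %in% names(psms)))
    stop("psms must have columns ", paste(need, collapse = ", "))
  if (nrow(psms) == 0) {
    warning("empty PSM table; returning empty protein set")
    return(character(0))
  }
  if (!any(psms$is_decoy))
    stop("target-decoy FDR estimation requires at least one decoy PSM")
  if (fdrThreshold < 0 || fdrThreshold > 1) stop("fdrThreshold outside [0, 1]")
  psms <- psms[psms$length >= minLength, , drop = FALSE]
  if (nrow(psms) == 0 || !any(!psms$is_decoy)) return(character(0))

  q <- .targetDecoyQ(psms$score, psms$is_decoy, conservative)
  keptPeptides <- !psms$is_decoy & q <= fdrThreshold

  # protein inference: best peptide score per (protein, decoy-status)
  bestIdx <- tapply(seq_len(nrow(psms)),
                    paste(psms$protein, psms$is_decoy),
                    function(ix) ix[which.max(psms$score[ix])])
  prot <- psms[unlist(bestIdx), , drop = FALSE]
  if (!any(prot$is_decoy))
    stop("no decoy proteins available for protein-level FDR")
  qProt <- .targetDecoyQ(prot$score, prot$is_decoy, conservative)
  keptProteins <- prot$protein[!prot$is_decoy & qProt <= fdrThreshold]

  .asSet(intersect(psms$protein[keptPeptides], keptProteins))
}

# q-values over score thresholds; decoys before targets at equal score
.targetDecoyQ <- function(score, isDecoy, conservative = FALSE) {
  ord <- order(-score, !isDecoy)
  d <- cumsum(isDecoy[ord])
  t <- cumsum(!isDecoy[ord])
  fdr <- if (conservative) (d + 1) / pmax(t, 1) else d / pmax(t, 1)
  fdr[t == 0] <- Inf
  q <- rev(cummin(rev(fdr)))
  q[order(ord)]
}

#' Normalize protein identifiers to gene symbols
#'
#' Uppercases, optionally strips everything after the first occurrence of an
#' isoform delimiter, and applies an optional raw-to-symbol mapping. Ids
#' without a mapping entry pass through unchanged with one summarizing
#' warning.
#'
#' @param rawIds character vector of identifiers.
#' @param mapping optional named character vector (names = raw ids, values =
#'   symbols); matching is case-insensitive.
#' @param isoformDelim optional single character; the suffix after its first
#'   occurrence is dropped (e.g. `"YWHAZ-2"` with `"-"` becomes `"YWHAZ"`).
#' @return sorted unique character vector of symbols.
#' @export
normalizeIdentifiers <- function(rawIds, mapping = NULL, isoformDelim = NULL) {
  ids <- toupper(trimws(as.character(rawIds)))
  if (!is.null(isoformDelim)) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", isoformDelim)
    ids <- sub(paste0(esc, ".*$"), "", ids)
  }
  if (!is.null(mapping)) {
    names(mapping) <- toupper(names(mapping))
    hit <- ids %in% names(mapping)
    if (any(!hit))
      warning(sum(!hit), " identifier(s) had no mapping entry and pass through unchanged")
    ids[hit] <- toupper(unname(mapping[ids[hit]]))
  }
  .asSet(ids)
}

#' Subtract a background proteome
#'
#' Plain set difference, used to remove the serum background common to all
#' secretome fractions.
#'
#' @param proteome,background character vectors of symbols.
#' @return sorted character vector `proteome \ background`.
#' @export
subtractBackground <- function(proteome, background) {
  .asSet(setdiff(.asSet(proteome), .asSet(background)))
}

#' Union of bioactive fraction proteomes
#'
#' @param fractions list of [FractionProteome-class] objects, all with
#'   activity `"bioactive"`.
#' @return sorted character vector of the union, with a `provenance`
#'   attribute mapping each protein to its contributing fraction ids.
#' @export
unionActive <- function(fractions) {
  if (!length(fractions)) stop("no fractions supplied")
  acts <- vapply(fractions, fractionActivity, character(1))
  if (!all(acts == "bioactive"))
    stop("unionActive expects only bioactive fractions; got activity: ",
         paste(unique(acts), collapse = ", "))
  u <- .asSet(unlist(lapply(fractions, fractionProteins)))
  prov <- lapply(setNames(u, u), function(p)
    unname(vapply(fractions[vapply(fractions, function(f)
      p %in% fractionProteins(f), logical(1))], function(f)
        f@fractionId, character(1))))
  attr(u, "provenance") <- prov
  u
}

#' Differential proteome between a secretome and a control
#'
#' @param secretome,control character vectors of symbols.
#' @return sorted character vector `secretome \ control`.
#' @export
differentialProteome <- function(secretome, control) {
  .asSet(setdiff(.asSet(secretome), .asSet(control)))
}

#' Intersect the two secretome experiments into a provenance-tracked report
#'
#' @param setA the background-subtracted bioactive union (optionally carrying
#'   a `provenance` attribute from [unionActive()]).
#' @param setB the differential proteome.
#' @return a [ProteinSetReport-class]; `intersection` is the candidate seed
#'   set of the funnel.
#' @export
intersectExperiments <- function(setA, setB) {
  a <- .asSet(setA); b <- .asSet(setB)
  inter <- intersect(a, b)
  prov <- attr(setA, "provenance")
  provOut <- lapply(setNames(inter, inter), function(p) {
    from <- if (!is.null(prov) && p %in% names(prov)) prov[[p]] else character(0)
    unique(c(from, "differential"))
  })
  new("ProteinSetReport", unionActive = a, differential = b,
      intersection = inter, provenance = provOut)
}
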