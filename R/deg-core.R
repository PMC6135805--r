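#' Trimmed-mean-of-M-values (TMM) library scaling factors
#'
#' The reference sample is the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile fraction. For every sample, gene-wise
#' log2 ratios (M) and average log2 abundances (A) against the reference are
#' computed over genes expressed in both; the stated fractions of extreme M
#' and A values are trimmed and the remaining M values are averaged with
#' inverse asymptotic-variance weights. Factors are normalized to geometric
#' mean 1.
#'
#' @param counts a [CountStudy-class] or a non-negative count matrix.
#' @param logratioTrim fraction of extreme M values trimmed at each end.
#' @param sumTrim fraction of extreme A values trimmed at each end.
#' @param doWeighting use inverse asymptotic-variance weights.
#' @param refColumn optional reference column index (overrides the
#'   upper-quartile rule).
#' @return named numeric vector of scaling factors (geometric mean 1).
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, sumTrim = 0.05,
                       doWeighting = TRUE, refColumn = NULL) {
  if (is(counts, "CountStudy")) counts <- countsMatrix(counts)
  x <- as.matrix(counts)
  lib <- colSums(x)
  if (any(lib <= 0)) stop("every sample must have a positive total count")
  f75 <- apply(x, 2, function(col) quantile(col, probs = 0.75)) / lib
  if (is.null(refColumn)) {
    refColumn <- if (stats::median(f75) < 1e-20) which.max(colSums(sqrt(x)))
                 else which.min(abs(f75 - mean(f75)))
  }
  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(x)))
  f <- vapply(seq_len(ncol(x)), function(i)
    .tmmPair(x[, i], x[, refColumn], lib[i], lib[refColumn],
             logratioTrim, sumTrim, doWeighting, ids[i]),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- ids
  f
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim, doWeighting,
                     sample) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR))
    stop("sample '", sample, "' shares no co-expressed genes with the reference")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (doWeighting)
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  else mean(logR[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + priorCount) / (effective library size in millions))`, where
#' the effective library size is the raw column total times its scaling
#' factor.
#'
#' @param counts a [CountStudy-class] or count matrix.
#' @param factors per-sample scaling factors (default all 1); see
#'   [tmmFactors()].
#' @param priorCount pseudocount added to every cell.
#' @return numeric matrix of log2 CPM values.
#' @export
cpmLog2 <- function(counts, factors = NULL, priorCount = 0.5) {
  if (is(counts, "CountStudy")) counts <- countsMatrix(counts)
  x <- as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(x))
  eff <- colSums(x) * factors
  log2(sweep(x + priorCount, 2, eff / 1e6, "/"))
}

#' Mean-abundance filter with CV diagnostics
#'
#' Keeps genes whose mean log2 abundance is at least `minMeanLog2`
#' (inclusive at the boundary) and reports the per-gene mean and linear-scale
#' coefficient of variation used to choose the threshold.
#'
#' @param expr log2 expression matrix.
#' @param minMeanLog2 threshold in log2 units.
#' @return list with `expr` (filtered matrix) and `diagnostics` (data.frame
#'   `gene`, `meanLog2`, `cv`).
#' @export
abundanceFilter <- function(expr, minMeanLog2 = 3.0) {
  m <- rowMeans(expr)
  lin <- 2^expr
  cv <- apply(lin, 1, sd) / rowMeans(lin)
  keep <- m >= minMeanLog2
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(expr)))
  list(expr = expr[keep, , drop = FALSE],
       diagnostics = data.frame(gene = ids, meanLog2 = unname(m),
                                cv = unname(cv),
                                row.names = NULL, stringsAsFactors = FALSE))
}

#' Vectorized per-gene one-way ANOVA
#'
#' Fixed-effects one-way ANOVA of each gene's expression across populations,
#' with exact F p-values.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param groups factor-like vector of population labels per sample.
#' @param dfLost residual degrees of freedom already consumed upstream (e.g.
#'   `nBatches - 1` when testing a batch-adjusted matrix); keeps the error
#'   variance estimate and the F reference distribution honest.
#' @return data.frame with columns `gene`, `F_statistic`, `p_value`.
#' @export
perGeneAnova <- function(expr, groups, dfLost = 0) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two populations")
  if (any(tabulate(groups) < 2)) stop("every population needs >= 2 samples")
  N <- ncol(expr)
  K <- nlevels(groups)
  if (N - K - dfLost < 1) stop("no residual degrees of freedom left")
  gm <- rowMeans(expr)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    idx <- groups == lev
    mk <- rowMeans(expr[, idx, drop = FALSE])
    ssb <- ssb + sum(idx) * (mk - gm)^2
    ssw <- ssw + rowSums((expr[, idx, drop = FALSE] - mk)^2)
  }
  Fst <- (ssb / (K - 1)) / (ssw / (N - K - dfLost))
  Fst[ssw == 0 & ssb == 0] <- 0
  Fst[ssw == 0 & ssb > 0] <- Inf
  p <- pf(Fst, K - 1, N - K - dfLost, lower.tail = FALSE)
  p[Fst == 0] <- 1
  data.frame(gene = rownames(expr), F_statistic = Fst, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-sample contrast t-statistic
#'
#' Pooled-variance two-sample t per gene; the sign is mean(`groupA`) minus
#' mean(`groupB`). A Welch variant is available by flag.
#'
#' @param expr log2 expression matrix.
#' @param groups population labels per sample.
#' @param groupA,groupB the two populations contrasted.
#' @param welch use the Welch (unequal-variance) form.
#' @param dfLost residual degrees of freedom consumed upstream (pooled form
#'   only); see [perGeneAnova()].
#' @return data.frame with columns `gene`, `t`, `df`, `p_value`.
#' @export
contrastTstat <- function(expr, groups, groupA, groupB, welch = FALSE,
                          dfLost = 0) {
  groups <- as.character(groups)
  ia <- groups == groupA
  ib <- groups == groupB
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both contrast groups need >= 2 samples")
  na <- sum(ia); nb <- sum(ib)
  xa <- expr[, ia, drop = FALSE]; xb <- expr[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2 - dfLost)
    se2 <- s2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2 - dfLost, nrow(expr))
  }
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0 & ma == mb] <- 0
  p <- 2 * pt(-abs(t), df)
  data.frame(gene = rownames(expr), t = t, df = df, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`), stable under
#' input permutation.
#'
#' @param pValues numeric vector of p-values.
#' @return numeric vector of q-values in `[0, 1]`.
#' @export
bhFdr <- function(pValues) p.adjust(pValues, method = "BH")

#' Call differentially expressed genes at an FDR threshold
#'
#' @param degResult a [DEGResult-class].
#' @param fdr q-value threshold (inclusive).
#' @return sorted character vector of DEG symbols.
#' @export
callDegs <- function(degResult, fdr = 0.05) {
  tb <- degTable(degResult)
  .asSet(tb$gene[tb$q_value <= fdr])
}

#' Run the full differential-expression core on a count study
#'
#' TMM normalization, log2 CPM, abundance filtering, optional additive batch
#' adjustment, per-gene one-way ANOVA across all populations, the two-group
#' contrast t-statistic, and BH FDR.
#'
#' @param study a [CountStudy-class].
#' @param groupA,groupB populations contrasted for the t-statistic; default
#'   the first two population levels.
#' @param minMeanLog2 abundance filter threshold (log2 CPM).
#' @param fdr FDR threshold for the `is_deg` flag.
#' @param adjustBatch remove additive batch effects before testing.
#' @param priorCount pseudocount for [cpmLog2()].
#' @param welch use Welch t for the contrast.
#' @return list with `deg` (a [DEGResult-class]), `expr` (the filtered,
#'   possibly batch-adjusted log2 CPM matrix), `factors` (TMM factors) and
#'   `diagnostics` (abundance-filter table).
#' @export
runDegAnalysis <- function(study, groupA = NULL, groupB = NULL,
                           minMeanLog2 = 3.0, fdr = 0.05,
                           adjustBatch = TRUE, priorCount = 0.5,
                           welch = FALSE) {
  ann <- sampleInfo(study)
  pops <- unique(ann$population)
  if (is.null(groupA)) groupA <- pops[1]
  if (is.null(groupB)) groupB <- pops[2]
  f <- tmmFactors(study)
  expr <- cpmLog2(study, f, priorCount = priorCount)
  filt <- abundanceFilter(expr, minMeanLog2)
  expr <- filt$expr
  dfLost <- 0
  if (adjustBatch && length(unique(ann$batch)) > 1) {
    expr <- adjustBatchEffects(expr, ann)
    dfLost <- length(unique(ann$batch)) - 1   # df consumed by the batch fit
  }
  aov <- perGeneAnova(expr, ann$population, dfLost = dfLost)
  ts <- contrastTstat(expr, ann$population, groupA, groupB, welch = welch,
                      dfLost = dfLost)
  q <- bhFdr(aov$p_value)
  tb <- data.frame(gene = aov$gene,
                   mean_log2 = rowMeans(expr),
                   F_statistic = aov$F_statistic,
                   contrast_t = ts$t,
                   p_value = aov$p_value,
                   q_value = q,
                   is_deg = q <= fdr,
                   row.names = NULL, stringsAsFactors = FALSE)
  deg <- new("DEGResult", table = tb, fdr = fdr,
             groups = c(groupA, groupB))
  list(deg = deg, expr = expr, factors = f, diagnostics = filt$diagnostics)
}
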