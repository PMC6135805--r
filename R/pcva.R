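#' Principal-component variance attribution (PCVA)
#'
#' Standardizes every gene, computes sample-space principal components, and
#' attributes the score variance of the first `nPcs` components to each
#' annotation factor by the R-squared of a one-way fit of the scores on that
#' factor. Per-factor contributions are the variance-weighted averages over
#' the retained components, expressed in percent; the residual is 100 minus
#' their sum (an exact partition only when the design factors are mutually
#' orthogonal).
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param annotation data.frame of per-sample design factors (e.g.
#'   `population`, `batch`, `subject`, `tissue`).
#' @param nPcs number of leading components attributed.
#' @return a [PcvaReport-class].
#' @export
pcva <- function(expr, annotation, nPcs = 3) {
  annotation <- as.data.frame(annotation)
  sds <- apply(expr, 1, sd)
  drop <- sds == 0
  if (any(drop)) {
    warning(sum(drop), " constant gene(s) excluded from PCVA")
    expr <- expr[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  Z <- (expr - rowMeans(expr)) / sds
  sv <- svd(t(Z))                       # rows = samples
  k <- min(nPcs, sum(sv$d > 1e-10))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  w <- sv$d[seq_len(k)]^2 / sum(sv$d[seq_len(k)]^2)
  factors <- names(annotation)
  perPc <- matrix(0, length(factors), k,
                  dimnames = list(factors, paste0("PC", seq_len(k))))
  for (f in factors) {
    fac <- factor(annotation[[f]])
    if (nlevels(fac) < 2) {
      warning("factor '", f, "' is constant across samples; contribution 0")
      next
    }
    perPc[f, ] <- vapply(seq_len(k), function(j)
      .onewayR2(scores[, j], fac), numeric(1))
  }
  contributions <- 100 * drop(perPc %*% w)
  new("PcvaReport",
      contributions = contributions,
      residual = 100 - sum(contributions),
      varianceExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
      perPc = perPc)
}

#' Remove additive batch effects while preserving population effects
#'
#' Fits, per gene, the additive two-factor linear model
#' `expression ~ population + batch`, and subtracts the estimated batch
#' component after centering it across samples so the grand mean is
#' preserved. Population effects are untouched. Errors when batch is aliased
#' with the biological variable.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param annotation data.frame with the biological and batch columns.
#' @param biologicalVar,batchVar column names in `annotation`.
#' @return adjusted expression matrix of the same shape.
#' @export
adjustBatchEffects <- function(expr, annotation,
                               biologicalVar = "population",
                               batchVar = "batch") {
  ann <- as.data.frame(annotation)
  bio <- factor(ann[[biologicalVar]])
  bat <- factor(ann[[batchVar]])
  if (nlevels(bat) < 2) {
    warning("single batch level; nothing to adjust")
    return(expr)
  }
  X <- model.matrix(~ bio + bat)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with ", biologicalVar,
         ": the additive design is aliased and batch effects are not identifiable")
  fit <- lm.fit(X, t(expr))
  bcols <- grep("^bat", colnames(X))
  be <- X[, bcols, drop = FALSE] %*% fit$coefficients[bcols, , drop = FALSE]
  be <- sweep(be, 2, colMeans(be))
  expr - t(be)
}
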