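#' Standardized least-square group means
#'
#' Computes per-gene group means (least-square means of the one-way model)
#' and z-standardizes each gene across groups (mean 0, sample SD 1), so
#' expression-level differences between genes do not dominate set-level
#' summaries. Constant genes become all-zero rows with a warning.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param groups group labels per sample.
#' @return gene x group matrix of standardized means.
#' @export
standardizeSlsm <- function(expr, groups) {
  groups <- factor(groups)
  means <- vapply(levels(groups), function(lev)
    rowMeans(expr[, groups == lev, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(expr))
  dimnames(means) <- list(rownames(expr), levels(groups))
  sds <- apply(means, 1, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " gene(s) constant across groups; standardized to 0")
  sds[flat] <- 1
  (means - rowMeans(means)) / sds
}

#' Gene-set eigengene (PC1) summary
#'
#' First principal component of a set's (row-centered) standardized profiles,
#' giving one score per group/sample. The sign is oriented to correlate
#' positively with the set's mean profile; for a singleton set the eigengene
#' is the row itself.
#'
#' @param slsm gene x group matrix (see [standardizeSlsm()]).
#' @param set character vector of member genes.
#' @return list with `scores` (named numeric per group), `varianceExplained`
#'   (share of set variance on PC1) and `nGenes` used.
#' @export
genesetPc1 <- function(slsm, set) {
  rows <- intersect(.asSet(set), rownames(slsm))
  if (!length(rows)) stop("no set members present in the matrix")
  X <- slsm[rows, , drop = FALSE]
  X <- X - rowMeans(X)
  sv <- svd(X)
  eigengene <- sv$d[1] * sv$v[, 1]
  meanProfile <- colMeans(X)
  if (sd(meanProfile) > 0 && sd(eigengene) > 0 &&
      cor(eigengene, meanProfile) < 0)
    eigengene <- -eigengene
  tot <- sum(sv$d^2)
  list(scores = setNames(eigengene, colnames(slsm)),
       varianceExplained = if (tot > 0) sv$d[1]^2 / tot else 1,
       nGenes = length(rows))
}

#' Ward hierarchical clustering with Newick serialization
#'
#' Agglomerative clustering of row profiles under the Ward variance
#' criterion (Euclidean distance, `ward.D2` linkage).
#'
#' @param profiles numeric matrix; rows are the objects clustered (e.g.
#'   gene-set eigengene profiles) and must be named.
#' @return list with `tree` (an `hclust` object) and `newick` (the tree as a
#'   Newick string with merge heights as branch lengths).
#' @export
wardCluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least two profiles to cluster")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("row", seq_len(nrow(profiles)))
  hc <- hclust(dist(profiles), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  list(tree = hc, newick = ape::write.tree(phy))
}
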