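# Independent brute-force oracles. These deliberately use naive O(N) loops /
# direct formulas so they share no code path with the package.

# GSEA enrichment score by walking the ranked list one gene at a time.
# scores must be sorted decreasingly; hits is a logical vector along it.
bruteEs <- function(scores, hits, p = 1) {
  w <- abs(scores)^p
  sw <- sum(w[hits])
  k <- sum(hits)
  N <- length(scores)
  run <- 0
  best <- 0
  worst <- 0
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) {
      if (sw > 0) w[i] / sw else 1 / k
    } else {
      -1 / (N - k)
    }
    if (run > best) best <- run
    if (run < worst) worst <- run
  }
  if (best >= -worst - 1e-9) best else worst
}

# BH step-up q-values by the double loop over the definition
bruteBh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)           # rank of p[i]
    cands <- vapply(r:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# one-way ANOVA F and p through stats::aov for a single response
anovaOracle <- function(y, g) {
  fit <- summary(aov(y ~ factor(g)))[[1]]
  c(F = fit$`F value`[1], p = fit$`Pr(>F)`[1])
}

# Ward (ward.D2) agglomeration by the Lance-Williams update, returning merge
# heights and the sets merged at each step
bruteWard <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2      # squared Euclidean
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  # ward.D2 cost between clusters via Lance-Williams on squared distances
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bestd) { bestd <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestd)
    merges[[step]] <- sort(unlist(members[c(i, j)]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# hypergeometric upper tail by explicit enumeration over choose()
bruteHyper <- function(k, Tn, U, Q) {
  kk <- k:min(Q, Tn)
  sum(choose(Tn, kk) * choose(U - Tn, Q - kk)) / choose(U, Q)
}

# per-fraction simulated study used by several files
makeTinyStudy <- function(seed = 1, ...) {
  net <- generatePpiNetwork(100, 300, 1, seed = seed)
  fac <- plantFactors(net, 3, 5, seed = seed)
  cs <- generateCounts(net, fac, nGenes = 400, samplesPerGroup = c(4, 4),
                       seed = seed, ...)
  list(network = net, factors = fac, study = cs$study, truth = cs$truth)
}
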