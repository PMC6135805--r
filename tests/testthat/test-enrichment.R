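rankedScores <- function(n, seed = 1) {
  withr::with_seed(seed, {
    s <- sort(rnorm(n), decreasing = TRUE)
    names(s) <- sprintf("g%03d", seq_len(n))
  })
  s
}

test_that("sets occupying the extreme ranks reach ES of exactly +-1", {
  sc <- rankedScores(40, seed = 51)
  top <- names(sc)[1:6]
  bottom <- names(sc)[35:40]
  res <- gseaTable(suppressWarnings(
    gseaPreranked(sc, list(top = top, bottom = bottom),
                  weightExponent = 0, nPerm = 100, seed = 1)))
  expect_equal(res$ES[res$pathway == "top"], 1)
  expect_equal(res$ES[res$pathway == "bottom"], -1)
  expect_identical(res$direction[res$pathway == "top"], "high")
  expect_identical(res$direction[res$pathway == "bottom"], "low")
})

test_that("ES matches the brute-force running-sum oracle on 200 random instances", {
  withr::with_seed(53, {
    for (i in 1:200) {
      N <- sample(15:50, 1)
      sc <- sort(rnorm(N), decreasing = TRUE)
      k <- sample(3:8, 1)
      hp <- sort(sample(N, k))
      hits <- seq_len(N) %in% hp
      p <- sample(0:1, 1)
      mine <- marrowNiche:::.gseaEs(hp, abs(sc[hp])^p, N)
      expect_equal(mine, bruteEs(sc, hits, p), tolerance = 1e-12)
    }
  })
})

test_that("negating all scores mirrors the enrichment score", {
  withr::with_seed(54, {
    for (i in 1:20) {
      N <- 30
      sc <- sort(rnorm(N), decreasing = TRUE)
      k <- 6
      hp <- sort(sample(N, k))
      es <- marrowNiche:::.gseaEs(hp, abs(sc[hp]), N)
      # reversing the ranking maps hit position j to N + 1 - j
      hpRev <- sort(N + 1 - hp)
      scRev <- sort(-sc, decreasing = TRUE)
      esRev <- marrowNiche:::.gseaEs(hpRev, abs(scRev[hpRev]), N)
      expect_equal(abs(esRev), abs(es), tolerance = 1e-9)
      # the positive-preference tie rule breaks the sign flip exactly when
      # the peak and trough magnitudes coincide; detect that from the curve
      w <- abs(sc[hp]); w <- w / sum(w)
      peaks <- cumsum(w) - (hp - seq_len(k)) / (N - k)
      tie <- abs(max(peaks) + min(peaks - w)) < 1e-9
      if (!tie) expect_equal(esRev, -es, tolerance = 1e-9)
    }
  })
})

test_that("ES agrees with the fgsea implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(55, {
    for (i in 1:50) {
      N <- sample(20:60, 1)
      sc <- sort(rnorm(N), decreasing = TRUE)
      names(sc) <- sprintf("g%03d", 1:N)
      k <- sample(3:8, 1)
      hp <- sort(sample(N, k))
      mine <- marrowNiche:::.gseaEs(hp, abs(sc[hp]), N)
      ref <- fgsea::calcGseaStat(sc, hp, gseaParam = 1)
      # the rare exact max/min tie is sign-ambiguous across implementations
      expect_equal(abs(mine), abs(ref), tolerance = 1e-12)
      if (abs(abs(mine) - abs(ref)) < 1e-12 && abs(mine + ref) > 1e-9)
        expect_equal(mine, ref, tolerance = 1e-12)
    }
  })
})

test_that("gseaPreranked is deterministic, bounded and flags tiny universes", {
  sc <- rankedScores(60, seed = 57)
  sets <- withr::with_seed(58, {
    s <- lapply(1:6, function(i) sample(names(sc), 10))
    names(s) <- paste0("S", 1:6)
    s
  })
  a <- gseaPreranked(sc, sets, nPerm = 200, seed = 5)
  b <- gseaPreranked(sc, sets, nPerm = 200, seed = 5)
  expect_identical(gseaTable(a), gseaTable(b))
  expect_true(all(abs(gseaTable(a)$ES) <= 1))
  expect_true(all(gseaTable(a)$q_value >= 0 & gseaTable(a)$q_value <= 1,
                  na.rm = TRUE))
  expect_warning(gseaPreranked(sc, sets, nPerm = 50, seed = 1), "unstable")
  expect_warning(
    gseaPreranked(sc, c(sets, list(alien = c("zz1", "zz2"))),
                  nPerm = 100, seed = 1),
    "no members")
  # leading edge stays inside the set and the ranked universe
  le <- leadingEdges(a)
  for (nm in names(le)) {
    expect_true(all(le[[nm]] %in% sets[[nm]]))
    expect_gt(length(le[[nm]]), 0)
  }
})

test_that("planted enriched sets are detected with high sensitivity", {
  sim <- makeTinyStudy(seed = 60, neighborDeProb = 0.7)
  run <- runDegAnalysis(sim$study, minMeanLog2 = 1)
  gs <- generateGeneSets(rownames(countsMatrix(sim$study)), nSets = 12,
                         sizeRange = c(20, 40), nEnriched = 4,
                         truth = sim$truth, enrichmentFactor = 5, seed = 61)
  tb <- degTable(run$deg)
  ranking <- setNames(tb$contrast_t, tb$gene)
  gt <- gseaTable(gseaPreranked(ranking, gs$collection, nPerm = 500,
                                seed = 62))
  hit <- gt$pathway[!is.na(gt$q_value) & gt$q_value <= 0.05]
  expect_gte(mean(enrichedSets(gs$truth) %in% hit), 0.75)
})

test_that("hypergeometric overlap matches enumeration", {
  uni <- sprintf("u%02d", 1:10)
  got <- hypergeometricOverlap(uni[1:5], uni[2:5], uni)
  expect_equal(got$overlap, 4)
  expect_equal(got$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(got$p_value, bruteHyper(4, 4, 10, 5), tolerance = 1e-12)
  full <- hypergeometricOverlap(uni, uni, uni)
  expect_equal(full$p_value, 1)
  expect_equal(full$overlap, 10)
  miss <- hypergeometricOverlap(uni[1:6], uni[7:10], uni)
  expect_equal(miss$overlap, 0)
  expect_equal(miss$p_value, 1, tolerance = 1e-12)
  withr::with_seed(63, {
    for (i in 1:20) {
      U <- sample(15:40, 1)
      uni <- sprintf("x%02d", seq_len(U))
      q <- sample(uni, sample(3:10, 1))
      t <- sample(uni, sample(3:10, 1))
      got <- hypergeometricOverlap(q, t, uni)
      expect_equal(got$p_value,
                   bruteHyper(got$overlap, length(t), U, length(q)),
                   tolerance = 1e-12)
    }
  })
})

test_that("standardized least-square means hit the two-group closed form", {
  expr <- rbind(g1 = c(1, 1, 5, 5), g2 = c(2, 2, 2, 2))
  g <- c("a", "a", "b", "b")
  expect_warning(z <- standardizeSlsm(expr, g), "constant")
  expect_equal(unname(z["g1", ]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z["g2", ]), c(0, 0))
  withr::with_seed(64, {
    expr2 <- matrix(rnorm(60), 10, 6,
                    dimnames = list(paste0("g", 1:10), NULL))
    g3 <- rep(c("a", "b", "c"), each = 2)
    z2 <- standardizeSlsm(expr2, g3)
    # oracle: per-gene scale() of the group means
    for (i in 1:10) {
      mns <- tapply(expr2[i, ], g3, mean)
      expect_equal(unname(z2[i, ]), as.numeric(scale(mns)),
                   tolerance = 1e-12)
    }
  })
})

test_that("gene-set eigengenes behave at the degenerate corners and match SVD", {
  z <- rbind(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1))
  colnames(z) <- c("g1", "g2", "g3")
  out <- genesetPc1(z, c("a", "b", "c"))
  expect_equal(out$varianceExplained, 1)
  expect_gt(cor(out$scores, c(-1, 0, 1)), 0.999)

  single <- genesetPc1(z, "a")
  expect_equal(unname(single$scores), c(-1, 0, 1))

  withr::with_seed(65, {
    m <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    out2 <- genesetPc1(m, paste0("g", 1:10))
    cm <- m - rowMeans(m)
    ref <- svd(cm)
    expect_equal(abs(out2$scores), abs(ref$d[1] * ref$v[, 1]),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(out2$varianceExplained, ref$d[1]^2 / sum(ref$d^2))
  })
  expect_error(genesetPc1(z, "nope"), "no set members")
})

test_that("Ward clustering reproduces hand merges and the Lance-Williams oracle", {
  x <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("p0", "p1", "p10"), NULL))
  out <- wardCluster(x)
  first <- sort(out$tree$labels[-out$tree$merge[1, ]])
  expect_identical(first, c("p0", "p1"))
  expect_match(out$newick, "p10")

  dup <- matrix(c(1, 1, 5, 1, 1, 5), 3, 2,
                dimnames = list(c("a", "b", "c"), NULL))
  outDup <- wardCluster(dup)
  expect_equal(outDup$tree$height[1], 0)

  withr::with_seed(66, {
    m <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(letters[1:8], NULL))
    hc <- wardCluster(m)$tree
    orc <- bruteWard(m)
    expect_equal(hc$height, orc$heights, tolerance = 1e-10)
    # identical merge heights under row permutation (tree isomorphism)
    perm <- sample(8)
    hc2 <- wardCluster(m[perm, ])$tree
    expect_equal(sort(hc2$height), sort(hc$height), tolerance = 1e-10)
  })
})

test_that("GSEA null calibration stays at or below the nominal set-level rate", {
  rates <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      uni <- sprintf("n%03d", 1:300)
      sc <- setNames(rnorm(300), uni)
      sets <- lapply(1:15, function(i) sample(uni, 20))
      names(sets) <- paste0("S", 1:15)
    })
    gt <- gseaTable(gseaPreranked(sc, sets, nPerm = 200, seed = 900 + s))
    mean(gt$q_value <= 0.05, na.rm = TRUE)
  }, numeric(1))
  mcse <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 2 * mcse)
})
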