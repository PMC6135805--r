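test_that("identical samples give unit TMM factors", {
  m <- matrix(rep(c(5, 20, 100, 3), 4), ncol = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_equal(unname(tmmFactors(m)), rep(1, 4))
})

test_that("a doubled library normalizes back to equal CPM", {
  withr::with_seed(31, {
    a <- rnbinom(500, mu = 100, size = 5) + 1
  })
  m <- cbind(A = a, B = 2 * a)
  f <- tmmFactors(m)
  cpm <- cpmLog2(m, f, priorCount = 0)
  expect_lt(max(abs(cpm[, "A"] - cpm[, "B"])), 1e-9)
})

test_that("TMM matches the edgeR oracle on random NB matrices", {
  skip_if_not_installed("edgeR")
  withr::with_seed(33, {
    for (i in 1:5) {
      m <- matrix(rnbinom(600 * 4, mu = exp(runif(600, 1, 6)), size = 5),
                  600, 4)
      mine <- unname(tmmFactors(m))
      ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  })
})

test_that("TMM errors on zero-total and no-overlap samples", {
  m <- cbind(a = c(0, 0), b = c(5, 5))
  expect_error(tmmFactors(m), "positive total")
  m2 <- cbind(a = c(10, 10, 0, 0), b = c(0, 0, 10, 10), c = c(5, 5, 5, 5))
  expect_error(tmmFactors(m2, refColumn = 1), "co-expressed")
})

test_that("log2 CPM follows the plug-in formula and is scale invariant", {
  m <- matrix(c(0, 999999.5), 2, 1,
              dimnames = list(c("zero", "rest"), "s"))
  # column total 999999.5, factor 1 -> effective size ~1e6
  got <- cpmLog2(m, factors = 1e6 / colSums(m), priorCount = 0.5)
  expect_equal(got["zero", 1], log2(0.5), tolerance = 1e-9)
  withr::with_seed(35, {
    m2 <- matrix(rnbinom(200, mu = 50, size = 5) + 1, 100, 2)
  })
  expect_equal(cpmLog2(m2, priorCount = 0), cpmLog2(2 * m2, priorCount = 0),
               tolerance = 1e-12)
})

test_that("abundance filter is inclusive at the boundary", {
  expr <- rbind(lo = rep(2.9, 4), at = rep(3.0, 4), hi = rep(3.1, 4))
  out <- abundanceFilter(expr, 3.0)
  expect_setequal(rownames(out$expr), c("at", "hi"))
  expect_named(out$diagnostics, c("gene", "meanLog2", "cv"))
  withr::with_seed(36, {
    e2 <- matrix(rnorm(600, mean = 3, sd = 1), 150, 4)
  })
  expect_equal(nrow(abundanceFilter(e2, 3)$expr),
               sum(rowMeans(e2) >= 3))
})

test_that("per-gene ANOVA reproduces the hand-computed example and aov", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  g <- rep(c("a", "b"), each = 3)
  out <- perGeneAnova(expr, g)
  expect_equal(out$F_statistic, 13.5)
  expect_equal(out$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(round(out$p_value, 4), 0.0213)
  # F equals t^2 for two groups
  ts <- contrastTstat(expr, g, "a", "b")
  expect_equal(ts$t^2, out$F_statistic)
  expect_equal(abs(ts$t), sqrt(13.5))
  # equal group means -> F = 0, p = 1
  eq <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  out0 <- perGeneAnova(eq, g)
  expect_equal(out0$F_statistic, 0)
  expect_equal(out0$p_value, 1)
})

test_that("vectorized ANOVA and t agree with stats::aov / t.test oracles", {
  withr::with_seed(37, {
    expr <- matrix(rnorm(30 * 9), 30, 9,
                   dimnames = list(paste0("g", 1:30), NULL))
    g <- rep(c("a", "b", "c"), each = 3)
    out <- perGeneAnova(expr, g)
    for (i in sample(30, 8)) {
      orc <- anovaOracle(expr[i, ], g)
      expect_equal(out$F_statistic[i], unname(orc["F"]), tolerance = 1e-10)
      expect_equal(out$p_value[i], unname(orc["p"]), tolerance = 1e-10)
    }
    g2 <- rep(c("a", "b"), c(5, 4))
    ts <- contrastTstat(expr, g2, "a", "b")
    for (i in sample(30, 8)) {
      orc <- t.test(expr[i, g2 == "a"], expr[i, g2 == "b"],
                    var.equal = TRUE)
      expect_equal(ts$t[i], unname(orc$statistic), tolerance = 1e-10)
      expect_equal(ts$p_value[i], orc$p.value, tolerance = 1e-10)
    }
    # antisymmetry under group swap
    expect_equal(contrastTstat(expr, g2, "b", "a")$t, -ts$t)
  })
})

test_that("BH q-values match the examples and the double-loop oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(0.123), 0.123)
  withr::with_seed(38, {
    for (i in 1:10) {
      p <- runif(sample(5:40, 1))^sample(1:3, 1)
      expect_equal(bhFdr(p), bruteBh(p), tolerance = 1e-12)
      perm <- sample(length(p))
      expect_equal(bhFdr(p[perm]), bhFdr(p)[perm])
    }
  })
})

test_that("callDegs respects the threshold and degenerate settings", {
  tb <- data.frame(gene = c("a", "b"), mean_log2 = 5, F_statistic = 1,
                   contrast_t = 1, p_value = c(0.001, 0.5),
                   q_value = c(0.002, 0.5), is_deg = c(TRUE, FALSE))
  dr <- new("DEGResult", table = tb, fdr = 0.05, groups = c("x", "y"))
  expect_identical(callDegs(dr), "a")
  expect_length(callDegs(dr, fdr = 0), 0)
  empty <- new("DEGResult", table = tb[0, ], fdr = 0.05,
               groups = c("x", "y"))
  expect_length(callDegs(empty), 0)
})

test_that("global-null simulations keep false DEG calls at or below the nominal rate", {
  frac <- vapply(1:50, function(s) {
    net <- generatePpiNetwork(30, 60, seed = 600 + s)
    fac <- plantFactors(net, 1, 2, seed = 600 + s)
    cs <- generateCounts(net, fac, nGenes = 200,
                         samplesPerGroup = c(4, 4), neighborDeProb = 0,
                         backgroundDeProb = 0, batchEffectSd = 0.5,
                         seed = 700 + s)
    run <- runDegAnalysis(cs$study)
    length(callDegs(run$deg)) / nrow(degTable(run$deg))
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
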