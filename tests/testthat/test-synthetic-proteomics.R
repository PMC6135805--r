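fac <- c("G000001", "G000007", "G000019")

test_that("zero dropout and zero contamination make the funnel exact", {
  fr <- generateFractionProteomes(fac, dropoutRate = 0, contaminantRate = 0,
                                  seed = 1)
  acts <- vapply(fr, fractionActivity, character(1))
  u <- unionActive(fr[acts == "bioactive"])
  bg <- fractionProteins(fr[[which(acts == "background")]])
  inact <- fractionProteins(fr[[which(acts == "inactive")[1]]])
  expect_setequal(subtractBackground(u, bg), fac)
  expect_setequal(
    differentialProteome(fractionProteins(fr[[1]]), inact), fac)
})

test_that("dropout 1 removes every factor from active fractions", {
  fr <- generateFractionProteomes(fac, dropoutRate = 1, seed = 2)
  for (f in fr[vapply(fr, fractionActivity, character(1)) == "bioactive"])
    expect_length(intersect(fractionProteins(f), fac), 0)
})

test_that("per-fraction factor recall matches the dropout rate binomially", {
  hits <- 0; total <- 0
  for (s in 1:100) {
    fr <- generateFractionProteomes(fac, dropoutRate = 0.1, seed = s)
    for (f in fr[vapply(fr, fractionActivity, character(1)) == "bioactive"]) {
      hits <- hits + length(intersect(fractionProteins(f), fac))
      total <- total + length(fac)
    }
  }
  p <- hits / total
  se <- sqrt(0.9 * 0.1 / total)
  expect_lt(abs(p - 0.9), 4 * se)
})

test_that("fraction generation rejects overlapping labels and bad rates", {
  expect_error(generateFractionProteomes(fac, activeLabels = c("x", "y"),
                                         inactiveLabels = c("y")), "disjoint")
  expect_error(generateFractionProteomes(fac, dropoutRate = 1.5), "rates")
})

test_that("with no true targets, target and decoy scores are exchangeable", {
  ok <- vapply(1:100, function(s) {
    tab <- generatePsmTable(nTrue = 0, nNullTargets = 400, nDecoys = 400,
                            seed = s)
    suppressWarnings(
      ks.test(tab$score[!tab$is_decoy], tab$score[tab$is_decoy])$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("PSM generator covers the length range and is deterministic", {
  a <- generatePsmTable(seed = 3)
  b <- generatePsmTable(seed = 3)
  expect_identical(a, b)
  expect_true(all(a$length >= 6 & a$length <= 30))
  expect_true(any(a$length < 7))   # the length filter has something to do
})

test_that("gene sets honor exact sizes and record enriched names in the truth", {
  sim <- makeTinyStudy(seed = 5)
  gs <- generateGeneSets(rownames(countsMatrix(sim$study)), nSets = 8,
                         sizeRange = c(15, 15), nEnriched = 3,
                         truth = sim$truth, enrichmentFactor = 4, seed = 5)
  expect_true(all(lengths(gs$collection) == 15))
  expect_length(enrichedSets(gs$truth), 3)
  expect_true(all(unlist(gs$collection) %in%
                  rownames(countsMatrix(sim$study))))
})

test_that("enriched sets carry the constructed DE excess; factor 1 gives none", {
  sim <- makeTinyStudy(seed = 6, neighborDeProb = 0.6,
                       backgroundDeProb = 0.05)
  genes <- rownames(countsMatrix(sim$study))
  deg <- plantedDeg(sim$truth)$gene
  deFrac <- length(deg) / length(genes)
  deIn <- function(gs) vapply(gs$collection, function(m)
    length(intersect(m, deg)), numeric(1))
  # enrichmentFactor 5: expected DE members ~ size * min(1, deFrac * 5)
  gs5 <- generateGeneSets(genes, nSets = 10, sizeRange = c(40, 40),
                          nEnriched = 5, truth = sim$truth,
                          enrichmentFactor = 5, seed = 7)
  cnt <- deIn(gs5)
  expected <- 40 * min(1, deFrac * 5)
  expect_lt(abs(mean(cnt[1:5]) - expected), 6)
  expect_gt(mean(cnt[1:5]), mean(cnt[6:10]) + 5)
  # enrichmentFactor 1: enriched and background sets indistinguishable
  cnts1 <- unlist(lapply(1:20, function(s) {
    deIn(generateGeneSets(genes, nSets = 2, sizeRange = c(40, 40),
                          nEnriched = 1, truth = sim$truth,
                          enrichmentFactor = 1, seed = 100 + s))
  }))
  enrichedMean <- mean(cnts1[seq(1, 40, 2)])
  plainMean <- mean(cnts1[seq(2, 40, 2)])
  expect_lt(abs(enrichedMean - plainMean), 3)
})

test_that("Elispot series follow the closed-form Poisson means", {
  # decay 0.1/day at day 7: mean spots = 100 * exp(-0.7) ~ 49.66
  el <- generateElispotSeries(
    data.frame(name = "a", day0Frac = 1, decayRate = 0.1),
    days = rep(7, 40), wellsPerDay = 10, maxSpots = 100, seed = 8)$a
  expect_lt(abs(mean(el$spots) - 100 * exp(-0.7)) /
            (sqrt(100 * exp(-0.7)) / sqrt(nrow(el))), 4)

  flat <- generateElispotSeries(
    data.frame(name = "a", day0Frac = 0.5, decayRate = 0),
    days = c(1, 2, 3, 7, 14), wellsPerDay = 50, maxSpots = 200, seed = 9)$a
  dayMeans <- tapply(flat$spots, flat$day, mean)
  expect_lt(max(abs(dayMeans - 100)), 4 * sqrt(100 / 50))

  dead <- generateElispotSeries(
    data.frame(name = "a", day0Frac = 1, decayRate = Inf),
    days = c(0, 1, 5), wellsPerDay = 4, maxSpots = 100, seed = 10)$a
  expect_true(all(dead$spots[dead$day > 0] == 0))
  expect_gt(mean(dead$spots[dead$day == 0]), 50)

  a <- generateElispotSeries(data.frame(name = "a", day0Frac = 1,
                                        decayRate = 0.2), seed = 11)
  b <- generateElispotSeries(data.frame(name = "a", day0Frac = 1,
                                        decayRate = 0.2), seed = 11)
  expect_identical(a, b)
})
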