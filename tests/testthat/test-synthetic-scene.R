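test_that("terrain generation is deterministic and rejects bad arguments", {
  a <- generateTerrain(64, 64, 25, 1, seed = 7)
  b <- generateTerrain(64, 64, 25, 1, seed = 7)
  expect_identical(handGrid(a), handGrid(b))
  expect_identical(forestMask(a), forestMask(b))
  expect_identical(drainageMask(a), drainageMask(b))
  c <- generateTerrain(64, 64, 25, 1, seed = 8)
  expect_false(identical(handGrid(a), handGrid(c)))
  expect_error(generateTerrain(4, 64, 25, 1, seed = 1), ">= 8")
  expect_error(generateTerrain(16, 16, -1, 1, seed = 1), "positive")
  expect_error(generateTerrain(16, 16, 25, 0, seed = 1), "nChannels")
})

test_that("HAND is zero on drainage and monotone in BFS channel distance", {
  for (seed in c(7, 21, 99)) {
    tm <- generateTerrain(8, 8, 25, 1, seed = seed)
    hand <- handGrid(tm)
    expect_true(all(hand[drainageMask(tm)] == 0))
    expect_true(all(hand >= 0))
    d <- bfsDistanceOracle(drainageMask(tm))
    # strictly farther from a channel (in BFS steps) => strictly larger HAND:
    # the largest HAND in each distance class sits below the smallest HAND
    # in the next
    steps <- sort(unique(as.vector(d)))
    classMax <- vapply(steps, function(k) max(hand[d == k]), numeric(1))
    classMin <- vapply(steps, function(k) min(hand[d == k]), numeric(1))
    expect_true(all(classMax[-length(steps)] < classMin[-1]))
  }
})

test_that("flood truth follows the cutoff trajectory", {
  tm <- smallTerrain()
  yrs <- 2007:2012

  # constant cutoff, no noise: identical grids every year
  constant <- generateFloodTruth(tm, floodDynamics(yrs, 1, 0, seed = 3))
  for (g in constant) expect_identical(g, constant[[1]])

  # positive trend, no noise: flooded count non-decreasing
  rising <- generateFloodTruth(
    tm, floodDynamics(yrs, 0.5, 0.3, seed = 3))
  counts <- vapply(rising, sum, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])

  # the same monotonicity holds with spatial heterogeneity (static field)
  hetero <- generateFloodTruth(
    tm, floodDynamics(yrs, 0.5, 0.3, spatialAnomalySdM = 0.4, seed = 3))
  expect_true(all(diff(vapply(hetero, sum, integer(1))) >= 0))

  # cutoff below the smallest positive HAND: only HAND-0 forest pixels flood
  hand <- handGrid(tm)
  minPos <- min(hand[hand > 0])
  low <- generateFloodTruth(tm, floodDynamics(2007L, minPos / 2, seed = 3))
  expect_identical(low[[1]], forestMask(tm) & hand == 0)

  # a cutoff that floods everything is a degenerate scene
  expect_error(
    generateFloodTruth(tm, floodDynamics(2007L, max(hand) + 1, seed = 3)),
    "degenerate")
})

test_that("flood truth is piecewise linear around the breakpoint", {
  dyn <- floodDynamics(2007:2024, 1.2, -0.05, breakpointYear = 2015L,
                       postBreakTrendMPerYear = 0.1)
  cuts <- swampflux:::floodCutoffs(dyn)
  yrs <- 2007:2024
  pre <- yrs <= 2015
  expect_equal(cuts[pre], 1.2 - 0.05 * (yrs[pre] - 2007))
  expect_equal(cuts[!pre], cuts[yrs == 2015] + 0.1 * (yrs[!pre] - 2015))
})

test_that("backscatter scenes have the configured class-conditional structure", {
  tm <- smallTerrain(n = 48)
  truth <- forestMask(tm) & handGrid(tm) <= 1.5

  # zero noise: exact class means
  p0 <- sceneParams(noiseSdDb = 0, seed = 5)
  sc0 <- generateBackscatter(tm, truth, p0, 2019L)
  expect_true(all(hhGrid(sc0)[truth] == -6))
  expect_true(all(hhGrid(sc0)[!truth] == -9))
  expect_true(all(hvGrid(sc0)[truth] == -12))

  # with noise: sample mean of flooded HH within 3 standard errors
  p1 <- sceneParams(noiseSdDb = 1, seed = 5)
  sc1 <- generateBackscatter(tm, truth, p1, 2019L)
  n <- sum(truth)
  expect_gte(n, 500)
  expect_lt(abs(mean(hhGrid(sc1)[truth]) - (-6)), 3 / sqrt(n))
  expect_lt(abs(mean(hvGrid(sc1)[!truth]) - (-13)), 3 / sqrt(sum(!truth)))

  # determinism and shape checking
  expect_identical(hhGrid(generateBackscatter(tm, truth, p1, 2019L)),
                   hhGrid(sc1))
  expect_error(generateBackscatter(tm, truth[1:10, 1:10], p1, 2019L),
               "shape")
  # dry HH mean above flooded HH mean violates the double-bounce convention
  expect_error(sceneParams(hhMeanFloodedDb = -9, hhMeanDryDb = -6),
               "double")
})

test_that("ground-truth sampling agrees with the truth grid", {
  tm <- smallTerrain(n = 48)
  truth <- forestMask(tm) & handGrid(tm) <= 2

  gt <- generateGroundTruth(truth, nPoints = 10, seed = 2)
  p <- groundTruthPoints(gt)
  expect_identical(p$label == "swamp", truth[cbind(p$row, p$col)])
  gt2 <- generateGroundTruth(truth, nPoints = 10, seed = 2)
  expect_identical(groundTruthPoints(gt2), p)

  # default point count matches the designed campaign size
  big <- generateGroundTruth(truth, seed = 2)
  expect_identical(nrow(groundTruthPoints(big)), 1087L)

  expect_error(generateGroundTruth(truth, nPoints = 1e6, seed = 1),
               "exceeds")
  expect_error(generateGroundTruth(matrix(TRUE, 4, 4), nPoints = 4, seed = 1),
               "both classes")
})

test_that("EVI stacks recover imposed trends and availability", {
  tm <- smallTerrain(n = 40)
  dyn <- floodDynamics(2011:2020, 1, 0, seed = 4)
  truth <- generateFloodTruth(tm, dyn)

  # constant series per pixel when trend and noise are zero
  flat <- generateEviStack(tm, truth, trendPerYear = 0, noiseSd = 0)
  forestIdx <- which(forestMask(tm))
  for (g in flat$evi) expect_equal(g[forestIdx], flat$evi[[1]][forestIdx])

  # noiseless imposed trend recovered exactly by per-pixel OLS
  trended <- generateEviStack(tm, truth, trendPerYear = 0.001, noiseSd = 0)
  px <- forestIdx[1]
  series <- vapply(trended$evi, `[`, numeric(1), px)
  fit <- olsTrend(2011:2020, series)
  expect_equal(trendSlope(fit), 0.001, tolerance = 1e-12)

  # swamp baseline below terra firme baseline
  freq <- trended$floodFrequency
  swampIdx <- which(freq == trended$nMaps & forestMask(tm))
  tfIdx <- which(freq == 0 & forestMask(tm))
  expect_lt(mean(trended$evi[[1]][swampIdx]), mean(trended$evi[[1]][tfIdx]))

  # missing fraction: mean availability within 3 binomial SEs of 0.7
  miss <- generateEviStack(tm, truth, missingFraction = 0.3, seed = 9)
  avail <- unlist(lapply(miss$available, function(a) a[forestIdx]))
  se <- sqrt(0.3 * 0.7 / length(avail))
  expect_lt(abs(mean(avail) - 0.7), 3 * se)
  expect_error(generateEviStack(tm, truth, missingFraction = 1), "\\[0, 1\\)")
})

test_that("the default flux table encodes the expected flux ordering", {
  ft <- defaultFluxTable()
  tb <- fluxValues(ft)
  expect_identical(sort(unique(tb$class)), sort(wtlClassLabels()))
  expect_identical(nrow(tb), 18L)
  expect_true(all(tb$ciLow <= tb$mean & tb$mean <= tb$ciHigh))

  ch4 <- tb[tb$gas == "CH4", ]
  ch4 <- ch4[match(wtlClassLabels(), ch4$class), ]
  co2 <- tb[tb$gas == "CO2", ]
  co2 <- co2[match(wtlClassLabels(), co2$class), ]
  # CH4 rises and CO2 falls with rising water table; deepest water emits
  # the most CH4
  expect_true(all(diff(ch4$mean) > 0))
  expect_true(all(diff(co2$mean) < 0))
  expect_gt(ch4$mean[6], ch4$mean[1])

  # round-trips through CSV
  f <- withr::local_tempfile(fileext = ".csv")
  writeFluxTable(ft, f)
  expect_equal(fluxValues(readFluxTable(f)), tb)

  # malformed tables are rejected
  bad <- tb[tb$class != wtlClassLabels()[1], ]
  expect_error(fluxTable(bad), "six")
})
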