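test_that("flood-potential mask keeps forest at HAND <= 20 m", {
  forest <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1)
  hand <- matrix(c(0, 20, 21, 0), 1)
  m <- floodPotentialMask(forest, hand, 20)
  expect_identical(as.vector(m), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(floodPotentialMask(forest, matrix(0, 2, 2)), "shape")
})

test_that("stratified 70/30 split has the documented sizes and is seeded", {
  feats <- separableFeatures(nPerClass = 200)
  # emulate the 1087-point campaign split: per-class rounding gives 760 or 761
  nSwamp <- 544; nDry <- 1087 - nSwamp
  nTrain <- round(nSwamp * 0.7) + round(nDry * 0.7)
  expect_true(nTrain %in% c(760L, 761L))

  cl1 <- trainFloodClassifier(feats, seed = 42, nTrees = 100)
  cl2 <- trainFloodClassifier(feats, seed = 42, nTrees = 100)
  expect_identical(confusionMatrix(accuracyReport(cl1)),
                   confusionMatrix(accuracyReport(cl2)))
  expect_identical(cl1@nTrain, 280L)
  expect_identical(cl1@nHoldout, 120L)

  oneClass <- feats[feats$label == "swamp", ]
  expect_error(trainFloodClassifier(oneClass, seed = 1), "both classes")
})

test_that("separable features give perfect holdout accuracy", {
  cl <- trainFloodClassifier(separableFeatures(nPerClass = 200), seed = 7)
  rep <- accuracyReport(cl)
  expect_equal(overallAccuracy(rep), 1.0)
  expect_equal(unname(rep@userAccuracy), c(1, 1))
  expect_equal(unname(rep@producerAccuracy), c(1, 1))
})

test_that("randomly shuffled labels give chance-level accuracy", {
  feats <- separableFeatures(nPerClass = 200)
  feats$label <- withr::with_seed(99, sample(feats$label))
  cl <- trainFloodClassifier(feats, seed = 7)
  # balanced classes, n = 120 holdout: within 3 SEs of 0.5
  se <- sqrt(0.25 / cl@nHoldout)
  expect_lt(abs(overallAccuracy(accuracyReport(cl)) - 0.5), 3 * se)
})

test_that("noise-free scenes are classified back to the exact truth", {
  tm <- smallTerrain(n = 32, seed = 13)
  dyn <- floodDynamics(2018:2020, 1.2, 0.2, spatialAnomalySdM = 0.3,
                       seed = 5)
  truth <- generateFloodTruth(tm, dyn)
  p0 <- sceneParams(noiseSdDb = 0, seed = 5)
  potential <- floodPotentialMask(forestMask(tm), handGrid(tm), 20)

  sc <- generateBackscatter(tm, truth[["2019"]], p0, 2019L)
  gt <- generateGroundTruth(truth[["2019"]], nPoints = 200, seed = 3,
                            eligibleMask = potential)
  feats <- extractFeatures(sc, handGrid(tm), gt)
  cl <- trainFloodClassifier(feats, seed = 11)

  for (yr in c("2018", "2020")) {
    scy <- generateBackscatter(tm, truth[[yr]], p0, as.integer(yr))
    fm <- classifyYear(cl, scy, handGrid(tm), potential)
    expect_identical(floodedMask(fm), truth[[yr]] & potential)
  }

  # all pixels invalid: empty map, zero area
  scBad <- generateBackscatter(tm, truth[["2019"]], p0, 2019L,
                               gapMask = matrix(TRUE, 32, 32))
  scBad <- applyQualityMask(scBad, 1L)
  fmEmpty <- classifyYear(cl, scBad, handGrid(tm), potential)
  expect_identical(sum(floodedMask(fmEmpty)), 0L)
  expect_equal(extentSeries(list(fmEmpty))$areaKm2, 0)
})

test_that("extent series is pixel count times pixel area", {
  g <- matrix(FALSE, 20, 20)
  g[1:10, 1:10] <- TRUE
  m <- mapFromGrid(g, px = 25)
  expect_equal(extentSeries(list(m))$areaKm2, 100 * 625 / 1e6)  # 0.0625

  g2 <- matrix(FALSE, 20, 20); g2[1:10, 1:20] <- TRUE
  expect_equal(extentSeries(list(mapFromGrid(g2, px = 25)))$areaKm2,
               2 * extentSeries(list(m))$areaKm2)
  expect_error(extentSeries(list()), "non-empty")
})

test_that("error-adjusted extent reduces to the mapped area in clean cases", {
  g <- matrix(FALSE, 20, 20); g[1:8, ] <- TRUE
  m <- mapFromGrid(g, px = 25)

  perfect <- new("AccuracyReport",
    confusion = matrix(c(50L, 0L, 0L, 50L), 2,
                       dimnames = list(c("swamp", "terra_firme"),
                                       c("swamp", "terra_firme"))),
    overall = 1, userAccuracy = c(swamp = 1, terra_firme = 1),
    producerAccuracy = c(swamp = 1, terra_firme = 1))
  est <- errorAdjustedExtent(m, perfect)
  expect_equal(est$areaKm2, est$mappedKm2)
  expect_equal(est$ciLowKm2, est$areaKm2)
  expect_equal(est$ciHighKm2, est$areaKm2)

  # symmetric confusion with equal mapped class areas: adjusted = mapped
  gHalf <- matrix(FALSE, 20, 20); gHalf[1:10, ] <- TRUE
  mHalf <- mapFromGrid(gHalf, px = 25)
  sym <- new("AccuracyReport",
    confusion = matrix(c(40L, 10L, 10L, 40L), 2,
                       dimnames = list(c("swamp", "terra_firme"),
                                       c("swamp", "terra_firme"))),
    overall = 0.8, userAccuracy = c(swamp = 0.8, terra_firme = 0.8),
    producerAccuracy = c(swamp = 0.8, terra_firme = 0.8))
  estSym <- errorAdjustedExtent(mHalf, sym)
  expect_equal(estSym$areaKm2, estSym$mappedKm2)
  expect_lt(estSym$ciLowKm2, estSym$areaKm2)
  expect_gt(estSym$ciHighKm2, estSym$areaKm2)
})

test_that("error-adjusted CI agrees with a bootstrap over holdout points", {
  g <- matrix(FALSE, 30, 30); g[1:12, ] <- TRUE
  m <- mapFromGrid(g, px = 25)
  cm <- matrix(c(70L, 12L, 18L, 100L), 2,
               dimnames = list(c("swamp", "terra_firme"),
                               c("swamp", "terra_firme")))
  rep <- new("AccuracyReport", confusion = cm,
             overall = sum(diag(cm)) / sum(cm),
             userAccuracy = diag(cm) / rowSums(cm),
             producerAccuracy = diag(cm) / colSums(cm))
  est <- errorAdjustedExtent(m, rep)

  # bootstrap oracle: resample each mapped stratum's holdout points and
  # recompute the stratified adjusted area
  total <- 900 * 625 / 1e6
  W <- c(12 * 30, 18 * 30) * 625 / 1e6 / total
  boot <- withr::with_seed(1, replicate(4000, {
    pSw <- c(mean(sample(c(rep(1, 70), rep(0, 18)), 88, TRUE)),
             mean(sample(c(rep(1, 12), rep(0, 100)), 112, TRUE)))
    sum(W * pSw) * total
  }))
  expect_equal(est$areaKm2, mean(boot), tolerance = 0.02)
  expect_equal(est$ciHighKm2 - est$ciLowKm2,
               unname(diff(quantile(boot, c(0.025, 0.975)))),
               tolerance = 0.08)
})

test_that("change map applies the strict-majority rule and partitions the domain", {
  base <- matrix(FALSE, 10, 10)
  a <- base; a[1:4, ] <- TRUE     # early flooding rows 1-4
  b <- base; b[3:6, ] <- TRUE     # late flooding rows 3-6

  same <- changeMap(list(mapFromGrid(a, 2007)), list(mapFromGrid(a, 2020)))
  expect_identical(unname(same$counts[c("flood_loss", "flood_gain")]),
                   c(0L, 0L))

  res <- changeMap(list(mapFromGrid(a, 2007)), list(mapFromGrid(b, 2020)))
  expect_identical(unname(res$counts["flood_loss"]), 20L)   # rows 1-2
  expect_identical(unname(res$counts["flood_gain"]), 20L)   # rows 5-6
  expect_identical(unname(res$counts["stable_swamp"]), 20L) # rows 3-4
  expect_identical(sum(res$counts), 100L)                   # partition

  # flooded in 3/4 early maps, 0/10 late maps => loss
  early <- lapply(1:4, function(i) mapFromGrid(if (i <= 3) a else base, 2006 + i))
  late <- lapply(1:10, function(i) mapFromGrid(base, 2014 + i))
  resMaj <- changeMap(early, late)
  expect_identical(unname(resMaj$counts["flood_loss"]), 40L)
  # flooded in 2/4 early maps is not a strict majority => no loss
  early2 <- lapply(1:4, function(i) mapFromGrid(if (i <= 2) a else base, 2006 + i))
  expect_identical(unname(changeMap(early2, late)$counts["flood_loss"]), 0L)
})
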