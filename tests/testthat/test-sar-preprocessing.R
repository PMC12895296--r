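test_that("digital numbers calibrate to gamma naught in dB", {
  g <- dnToGamma0(matrix(c(1, 10, 0, 100), 2), calibrationFactorDb = -83)
  expect_equal(g[1, 1], -83)            # log10(1) = 0
  expect_equal(g[2, 1], -63)            # 10*log10(100) - 83
  expect_equal(g[2, 2], 10 * log10(1e4) - 83)
  expect_true(is.na(g[1, 2]))           # DN 0 masked, not -Inf
  expect_error(dnToGamma0(matrix(-1)), ">= 0")
})

test_that("incidence-angle correction matches the cosine model and round-trips", {
  m <- matrix(0, 3, 3)
  expect_identical(correctIncidenceAngle(m, 38.7, 38.7), m)
  corr <- correctIncidenceAngle(matrix(0, 1, 1), 45, 38.7)
  expect_equal(corr[1, 1],
               -10 * log10(cos(45 * pi / 180) / cos(38.7 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(corr[1, 1], 0.4285, tolerance = 1e-3)

  # correction then inverse correction restores the input
  g <- matrix(rnorm(25, -8), 5, 5)
  inc <- matrix(runif(25, 20, 50), 5, 5)
  fwd <- correctIncidenceAngle(g, inc, 38.7)
  rt <- fwd + 10 * log10(cos(inc * pi / 180) / cos(38.7 * pi / 180))
  expect_lt(max(abs(rt - g)), 1e-9)
  expect_error(correctIncidenceAngle(g, matrix(95, 5, 5)), "between 0 and 90")
})

test_that("speckle filtering averages valid neighbours only", {
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_equal(speckleFilter(m)[2, 2], 1)        # 9/9 window mean
  expect_equal(speckleFilter(m)[1, 1], 9 / 4)    # corner window of 4

  const <- matrix(4.2, 6, 6)
  expect_equal(speckleFilter(const), const)
  expect_identical(speckleFilter(const, kernel = 1), const)
  expect_error(speckleFilter(const, kernel = 2), "odd")

  # linearity: filtering commutes with adding a constant (dB domain)
  g <- matrix(rnorm(64), 8, 8)
  expect_equal(speckleFilter(g + 3), speckleFilter(g) + 3)

  # NA pixels are excluded from windows and stay NA
  g[3, 3] <- NA
  f <- speckleFilter(g)
  expect_true(is.na(f[3, 3]))
  expect_equal(f[2, 2], mean(g[1:3, 1:3], na.rm = TRUE))

  # median variant
  expect_equal(speckleFilter(m, stat = "median")[2, 2], 0)
})

test_that("quality masking invalidates flagged pixels without touching values", {
  tm <- smallTerrain(n = 16)
  truth <- forestMask(tm) & handGrid(tm) <= 1
  sc <- generateBackscatter(tm, truth, sceneParams(seed = 2), 2019L)
  expect_identical(applyQualityMask(sc), sc)  # no bad flags present

  sc@qualityFlags[1, 1] <- 1L
  sc@qualityFlags[2, 2] <- 7L
  m1 <- applyQualityMask(sc, badFlagValues = 1L)
  expect_identical(sum(!validMask(m1)), 1L)
  m2 <- applyQualityMask(sc, badFlagValues = c(1L, 7L))
  expect_identical(sum(!validMask(m2)), 2L)
  expect_identical(hhGrid(m2), hhGrid(sc))

  # toy 2x2: one flagged pixel leaves exactly 3 valid
  toy <- sc
  toy@hhDb <- toy@hhDb[1:2, 1:2]; toy@hvDb <- toy@hvDb[1:2, 1:2]
  toy@incidenceDeg <- toy@incidenceDeg[1:2, 1:2]
  toy@qualityFlags <- matrix(c(0L, 1L, 0L, 0L), 2)
  toy@validMask <- matrix(TRUE, 2, 2)
  toy@filledMask <- matrix(FALSE, 2, 2)
  expect_identical(sum(validMask(applyQualityMask(toy, 1L))), 3L)
})

test_that("gap filling takes donor values and records provenance", {
  tm <- smallTerrain(n = 16)
  truth <- forestMask(tm) & handGrid(tm) <= 1
  t2008 <- generateBackscatter(tm, truth, sceneParams(seed = 2), 2008L)
  t2007 <- generateBackscatter(tm, truth, sceneParams(seed = 2), 2007L)

  expect_identical(fillGaps(t2008, t2007), t2008)  # fully valid: unchanged

  gapped <- t2008
  gapped@validMask[3, 4] <- FALSE
  filled <- fillGaps(gapped, t2007)
  expect_identical(sum(filledMask(filled)), 1L)
  expect_equal(hhGrid(filled)[3, 4], hhGrid(t2007)[3, 4])
  expect_true(validMask(filled)[3, 4])

  allBad <- t2008
  allBad@validMask[] <- FALSE
  restored <- fillGaps(allBad, t2007)
  expect_equal(hhGrid(restored), hhGrid(t2007))
  expect_identical(sceneYear(restored), 2008L)
  expect_true(all(filledMask(restored)))

  expect_error(fillGaps(t2008, t2008), "differ")
})

test_that("no preprocessing operator revalidates an invalid pixel except fillGaps", {
  tm <- smallTerrain(n = 16)
  truth <- forestMask(tm) & handGrid(tm) <= 1
  sc <- generateBackscatter(tm, truth, sceneParams(seed = 3), 2019L,
                            gapMask = handGrid(tm) > 3)
  pp <- preprocessScene(sc, badFlagValues = 1L)
  expect_true(all(which(!validMask(sc) | sc@qualityFlags == 1L) %in%
                  which(!validMask(pp))))
  expect_true(all(is.finite(hhGrid(pp)[validMask(pp)])))
})
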