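test_that("OLS trend matches the closed form and handles degenerate series", {
  yrs <- 2001:2010
  exact <- olsTrend(yrs, 2 * yrs + 5)
  expect_equal(trendSlope(exact), 2, tolerance = 1e-12)
  expect_equal(unname(trendCi(exact)), c(2, 2))
  expect_lt(trendPValue(exact), 1e-12)

  flat <- olsTrend(yrs, rep(7, 10))
  expect_equal(trendSlope(flat), 0)
  expect_equal(trendPValue(flat), 1)

  expect_error(olsTrend(2001:2002, c(1, 2)), "at least 3")
  expect_error(olsTrend(c(2001, 2001, 2002), c(1, 2, 3)), "distinct")

  # oracle: normal equations, to 1e-10 relative error
  withr::with_seed(2, {
    x <- c(2007:2010, 2015:2024)
    y <- 1528 * x + rnorm(14, sd = 3500)
    fit <- olsTrend(x, y)
    # normal equations on centred years (well-conditioned closed form)
    xc <- x - mean(x)
    beta <- solve(t(cbind(1, xc)) %*% cbind(1, xc), t(cbind(1, xc)) %*% y)
    expect_equal(trendSlope(fit), unname(beta[2, 1]), tolerance = 1e-10)
    expect_equal(fit@intercept, unname(beta[1, 1] - beta[2, 1] * mean(x)),
                 tolerance = 1e-10)
    # and against lm's t inference
    lmFit <- summary(lm(y ~ x))
    expect_equal(trendPValue(fit), lmFit$coefficients["x", 4],
                 tolerance = 1e-10)
    ci <- confint(lm(y ~ x))["x", ]
    expect_equal(unname(trendCi(fit)), unname(ci), tolerance = 1e-10)
  })
})

test_that("piecewise fit recovers a noiseless kink exactly and never beats a line at collinear data", {
  yrs <- 2001:2015
  v <- ifelse(yrs <= 2010, 100 - 5 * (yrs - 2001), 55 + 8 * (yrs - 2010))
  fit <- piecewiseTrend(yrs, v)
  expect_identical(breakpointYear(fit), 2010L)
  expect_equal(unname(trendSlope(fit)), c(-5, 8), tolerance = 1e-9)
  expect_lt(fit@rss, 1e-18)

  line <- piecewiseTrend(yrs, 3 * yrs + 1)
  expect_equal(unname(trendSlope(line)[1]), unname(trendSlope(line)[2]),
               tolerance = 1e-9)
  singleRss <- sum(lm(I(3 * yrs + 1) ~ yrs)$residuals^2)
  expect_lt(abs(line@rss - singleRss), 1e-15)

  expect_error(piecewiseTrend(2001:2005, 1:5), "at least 6")

  # piecewise RSS <= single-line RSS on noisy series
  withr::with_seed(5, {
    for (i in 1:20) {
      y <- rnorm(12)
      pw <- piecewiseTrend(2001:2012, y)
      lf <- lm(y ~ I(2001:2012))
      expect_lte(pw@rss, sum(lf$residuals^2) + 1e-12)
    }
  })
})

test_that("pixel-wise trends equal per-pixel OLS and summarise significance", {
  yrs <- 2001:2012
  withr::with_seed(9, {
    stack <- lapply(yrs, function(y)
      matrix(rnorm(25, mean = 0.01 * y), 5, 5))
    stack[[3]][2, 2] <- NA  # one missing observation
  })
  pt <- pixelwiseTrends(stack, yrs)
  for (r in 1:5) for (cc in 1:5) {
    series <- vapply(stack, `[`, numeric(1), r, cc)
    fit <- olsTrend(yrs, series)
    expect_equal(pt$slope[r, cc], trendSlope(fit), tolerance = 1e-12)
    expect_equal(pt$pValue[r, cc], trendPValue(fit), tolerance = 1e-12)
  }

  flatStack <- lapply(yrs, function(y) matrix(1, 4, 4))
  ptFlat <- pixelwiseTrends(flatStack, yrs)
  expect_equal(ptFlat$summary$fracIncreasing, 0)
  expect_equal(ptFlat$summary$fracDecreasing, 0)

  # mixture: 10% of pixels trended strongly, the rest pure noise; the
  # positive-significant fraction sits near 0.10 + (alpha/2) * 0.90
  withr::with_seed(31, {
    nPix <- 2500
    trended <- rep(c(TRUE, FALSE), c(250, 2250))
    stackMix <- lapply(seq_along(yrs), function(i)
      matrix(ifelse(trended, 0.05 * yrs[i], 0) + rnorm(nPix, sd = 0.05),
             50, 50))
  })
  s <- pixelwiseTrends(stackMix, yrs)$summary
  expFrac <- 0.10 + 0.025 * 0.90
  se <- sqrt(expFrac * (1 - expFrac) / nPix)
  expect_lt(abs(s$fracIncreasing - expFrac), 3 * se)
})

test_that("AMJ compositing averages April-June and enforces availability", {
  nr <- 4; nc <- 4
  months <- rep(c(3, 4, 5, 6), times = 3)        # March excluded
  years <- rep(2001:2003, each = 4)
  stack <- lapply(seq_along(months), function(i) {
    m <- matrix(0.4 + 0.1 * (months[i] - 4), nr, nc)
    m
  })
  # pixel (1,1): AMJ values 0.4, 0.5, 0.6 every year -> annual mean 0.5
  cmp <- amjComposite(stack, months, years)
  expect_equal(cmp$evi[["2001"]][1, 1], 0.5)
  expect_equal(cmp$evi[["2003"]][4, 4], 0.5)
  expect_identical(cmp$years, 2001:2003)

  # pixel available in fewer than 80% of AMJ observations is masked everywhere
  stack2 <- stack
  for (i in which(months %in% c(4, 5))[1:2]) stack2[[i]][2, 2] <- NA  # 7/9 = 78%
  cmp2 <- amjComposite(stack2, months, years)
  expect_false(cmp2$kept[2, 2])
  expect_true(all(is.na(vapply(cmp2$evi, `[`, numeric(1), 2, 2))))
  expect_true(cmp2$kept[1, 1])
  # exactly 80% availability is retained
  expect_equal(cmp2$availability[2, 2], 7 / 9)

  expect_error(amjComposite(stack, rep(1, 12), years), "April")
})

test_that("stratum means split by flood frequency and flag empty strata", {
  freq <- matrix(c(3, 3, 0, 0, 1, 2), 2, 3)  # swamp cols 1, tf col 2, mixed col 3
  evi <- list(matrix(0.45 * (freq == 3) + 0.50 * (freq == 0) +
                     0.47 * (freq %in% 1:2), 2, 3))
  s <- stratumMeans(evi, 2001, freq, nMaps = 3)
  expect_equal(s$swamp, 0.45)
  expect_equal(s$terra_firme, 0.50)
  expect_equal(s$all, mean(evi[[1]]))
  expect_warning(stratumMeans(evi, 2001, matrix(c(3, 1, 1, 1, 1, 1), 2, 3), 3),
                 "terra firme")
})

test_that("paired t-test handles shifts, identity and degenerate variance", {
  a <- c(0.45, 0.46, 0.44, 0.45, 0.47)
  same <- pairedTTest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)

  shifted <- pairedTTest(a, a + 0.05)   # b above a: negative t, p -> 0
  expect_identical(shifted$statistic, -Inf)
  expect_equal(shifted$pValue, 0)

  # agrees with stats::t.test in the regular case
  withr::with_seed(4, {
    b <- a + rnorm(5, 0.02, 0.01)
    ours <- pairedTTest(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$pValue, ref$p.value, tolerance = 1e-12)
  })

  # power: a swamp deficit of 0.05 at SD 0.01 over 14 years is detected
  # essentially always
  hits <- withr::with_seed(12, {
    mean(replicate(200, {
      sw <- rnorm(14, 0.45, 0.01)
      tf <- sw + 0.05 + rnorm(14, 0, 0.01)
      pairedTTest(sw, tf)$pValue < 0.05
    }))
  })
  expect_gte(hits, 0.99)
})
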