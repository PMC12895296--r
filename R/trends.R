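# Closed-form OLS of y on x with t-based inference; shared by olsTrend and
# pixelwiseTrends so the two agree exactly.
.olsCore <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((y - intercept - slope * x)^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
    ciLow <- ciHigh <- slope
  } else {
    tStat <- slope / se
    p <- 2 * stats::pt(-abs(tStat), df)
    tc <- stats::qt(0.975, df)
    ciLow <- slope - tc * se
    ciHigh <- slope + tc * se
  }
  list(slope = slope, intercept = intercept, se = se, pValue = p,
       ciLow = ciLow, ciHigh = ciHigh, rss = rss, n = n)
}

#' Ordinary-least-squares trend of an annual series
#'
#' OLS slope with a two-sided 95% confidence interval and p-value from the
#' t distribution on n - 2 degrees of freedom. Missing years are simply
#' absent from the fit — no imputation — so an observation gap (e.g.
#' 2011-2014) just reduces n.
#'
#' @param years numeric vector of distinct years.
#' @param values numeric vector, same length; NA pairs are dropped.
#' @return a [TrendFit-class].
#' @examples
#' fit <- olsTrend(2001:2010, 2 * (2001:2010) + 5)
#' trendSlope(fit)
#' @export
olsTrend <- function(years, values) {
  keep <- !is.na(years) & !is.na(values)
  years <- years[keep]; values <- values[keep]
  if (length(years) < 3L) .stopf("need at least 3 observations (got %d)",
                                 length(years))
  if (anyDuplicated(years)) .stopf("years must be distinct")
  f <- .olsCore(as.numeric(years), as.numeric(values))
  methods::new("TrendFit", slope = f$slope, intercept = f$intercept,
               slopeCiLow = f$ciLow, slopeCiHigh = f$ciHigh,
               pValue = f$pValue, n = as.integer(f$n))
}

#' One-breakpoint piecewise (segmented) trend
#'
#' Continuous two-segment linear fit
#' \eqn{y = b_0 + b_1 t + b_2 (t - \tau)_+}, with the breakpoint \eqn{\tau}
#' chosen by exhaustive search over the interior observed years minimising
#' the residual sum of squares; ties break toward the earliest year. The
#' pre-break slope is \eqn{b_1} and the post-break slope \eqn{b_1 + b_2}.
#' Because the single line is nested in every candidate model, the
#' piecewise RSS never exceeds the single-segment RSS.
#'
#' @param years numeric vector of distinct years (n >= 6).
#' @param values numeric vector, same length.
#' @return a [PiecewiseFit-class].
#' @examples
#' y <- c(10:6, 7:14)  # V-shape with the kink at the 5th year
#' piecewiseTrend(2001:2013, y)
#' @export
piecewiseTrend <- function(years, values) {
  keep <- !is.na(years) & !is.na(values)
  years <- as.numeric(years[keep]); values <- as.numeric(values[keep])
  if (length(years) < 6L) .stopf("need at least 6 observations (got %d)",
                                 length(years))
  if (anyDuplicated(years)) .stopf("years must be distinct")
  o <- order(years)
  years <- years[o]; values <- values[o]
  n <- length(years)
  candidates <- years[2:(n - 1L)]
  best <- NULL
  for (bp in candidates) {
    hinge <- pmax(years - bp, 0)
    X <- cbind(1, years, hinge)
    fit <- stats::lm.fit(X, values)
    if (any(is.na(fit$coefficients))) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(bp = bp, rss = rss, coef = fit$coefficients)
    }
  }
  if (is.null(best)) .stopf("no full-rank candidate breakpoint found")
  methods::new("PiecewiseFit",
    breakpointYear = as.integer(best$bp),
    slopePre = best$coef[[2L]],
    slopePost = best$coef[[2L]] + best$coef[[3L]],
    intercept = best$coef[[1L]],
    rss = best$rss, n = as.integer(n))
}

#' Pixel-wise trend maps over a raster stack
#'
#' Fits the same OLS as [olsTrend()] independently at every pixel with at
#' least 3 valid observations, and summarises the fraction of valid pixels
#' with p below \code{alpha}, split by slope sign (raw p values, no
#' multiplicity adjustment, unless \code{fdrAdjust}).
#'
#' @param stack list of numeric matrices (one per year; NA = missing).
#' @param years numeric vector, one year per stack entry.
#' @param alpha significance level (default 0.05).
#' @param fdrAdjust if TRUE, apply a Benjamini-Hochberg adjustment to the
#'   pixel p values before thresholding (off by default).
#' @return list: \code{slope} and \code{pValue} matrices (NA where fewer
#'   than 3 valid years), \code{nValid} matrix, and \code{summary} with
#'   \code{fracIncreasing}, \code{fracDecreasing} (significant fractions)
#'   and \code{nPixels}.
#' @export
pixelwiseTrends <- function(stack, years, alpha = 0.05, fdrAdjust = FALSE) {
  stopifnot(length(stack) == length(years))
  nr <- nrow(stack[[1L]]); nc <- ncol(stack[[1L]])
  Y <- vapply(stack, as.vector, numeric(nr * nc))  # pixels x years
  valid <- !is.na(Y)
  n <- rowSums(valid)
  x <- as.numeric(years)
  X <- matrix(x, nrow(Y), length(x), byrow = TRUE)
  X[!valid] <- 0
  Y0 <- Y; Y0[!valid] <- 0
  sumX <- rowSums(X); sumY <- rowSums(Y0)
  xbar <- sumX / n; ybar <- sumY / n
  sxx <- rowSums((X - xbar)^2 * valid)
  sxy <- rowSums((X - xbar) * (Y0 - ybar * valid))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  resid <- (Y0 - intercept - slope * X) * valid
  rss <- rowSums(resid^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tStat <- slope / se
  p <- 2 * stats::pt(-abs(tStat), df)
  zeroSe <- !is.na(se) & se == 0
  p[zeroSe & slope == 0] <- 1
  p[zeroSe & slope != 0] <- 0
  ok <- !is.na(sxx) & n >= 3L & sxx > 0
  slope[!ok] <- NA_real_
  p[!ok] <- NA_real_
  pThresh <- p
  if (fdrAdjust) pThresh[ok] <- stats::p.adjust(p[ok], method = "BH")
  nPix <- sum(ok)
  fracInc <- sum(pThresh[ok] < alpha & slope[ok] > 0) / nPix
  fracDec <- sum(pThresh[ok] < alpha & slope[ok] < 0) / nPix
  list(
    slope = matrix(slope, nr, nc),
    pValue = matrix(p, nr, nc),
    nValid = matrix(n, nr, nc),
    summary = list(fracIncreasing = fracInc, fracDecreasing = fracDec,
                   nPixels = nPix)
  )
}

#' April-May-June composite with an availability filter
#'
#' Per-pixel annual mean over the April, May and June images, after masking
#' pixels whose data availability across the whole AMJ time series falls
#' below the threshold (default 80%: a pixel available in less than 80% of
#' AMJ observations is removed from every year).
#'
#' @param stack list of numeric matrices (monthly images; NA = missing).
#' @param months integer vector (1-12), one per stack entry.
#' @param years integer vector, one per stack entry.
#' @param availabilityThreshold minimum availability fraction (default 0.8).
#' @return list: \code{years}, \code{evi} (per-year mean matrices),
#'   \code{availability} (per-pixel fraction), \code{kept} (logical matrix).
#' @export
amjComposite <- function(stack, months, years, availabilityThreshold = 0.8) {
  stopifnot(length(stack) == length(months), length(stack) == length(years))
  amj <- months %in% c(4L, 5L, 6L)
  if (!any(amj)) .stopf("no April-June images in the stack")
  stack <- stack[amj]; years <- years[amj]
  nr <- nrow(stack[[1L]]); nc <- ncol(stack[[1L]])
  availCount <- Reduce(`+`, lapply(stack, function(m) !is.na(m) + 0L))
  availability <- availCount / length(stack)
  kept <- availability >= availabilityThreshold
  yrs <- sort(unique(years))
  evi <- lapply(yrs, function(y) {
    sub <- stack[years == y]
    s <- Reduce(`+`, lapply(sub, function(m) { m[is.na(m)] <- 0; m }))
    cnt <- Reduce(`+`, lapply(sub, function(m) !is.na(m) + 0L))
    out <- s / cnt
    out[cnt == 0 | !kept] <- NA_real_
    out
  })
  names(evi) <- as.character(yrs)
  list(years = yrs, evi = evi, availability = availability, kept = kept)
}

#' Stratum mean series by flood frequency
#'
#' Mean EVI per year for all forest pixels, for always-flooded pixels
#' (frequency N/N: swamp) and never-flooded pixels (0/N: terra firme).
#' Intermediate-frequency pixels contribute only to the "all" series. An
#' empty stratum is flagged with a warning and its series set to NA.
#'
#' @param eviAnnual list of per-year EVI matrices (NA = masked).
#' @param years numeric vector of years.
#' @param floodFrequency integer matrix of flooded-year counts per pixel.
#' @param nMaps the number of maps behind \code{floodFrequency}.
#' @return data.frame: \code{year}, \code{all}, \code{swamp},
#'   \code{terra_firme}.
#' @export
stratumMeans <- function(eviAnnual, years, floodFrequency, nMaps) {
  swamp <- floodFrequency == nMaps
  tf <- floodFrequency == 0L
  if (!any(swamp)) warning("empty swamp stratum (no always-flooded pixels)")
  if (!any(tf)) warning("empty terra firme stratum (no never-flooded pixels)")
  strat <- function(m, mask) {
    if (!any(mask)) return(NA_real_)
    mean(m[mask], na.rm = TRUE)
  }
  data.frame(
    year = as.numeric(years),
    all = vapply(eviAnnual, function(m) mean(m, na.rm = TRUE), numeric(1)),
    swamp = vapply(eviAnnual, strat, numeric(1), mask = swamp),
    terra_firme = vapply(eviAnnual, strat, numeric(1), mask = tf),
    row.names = NULL
  )
}

#' Paired t-test on two annual series
#'
#' Classic paired t on the per-year differences \code{a - b}, two-sided by
#' default. Degenerate cases are resolved deterministically: zero-variance
#' differences with a non-zero mean give an infinite statistic and p = 0
#' (reported limit); all-zero differences give t = 0, p = 1.
#'
#' @param a,b numeric vectors of equal length (n >= 3).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (alternatives on mean(a - b)).
#' @return list: \code{statistic}, \code{pValue}, \code{df},
#'   \code{meanDiff}.
#' @export
pairedTTest <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 3L) .stopf("need at least 3 paired observations")
  m <- mean(d); s <- stats::sd(d)
  df <- n - 1L
  degenerate <- s == 0 || s < abs(m) * 1e-12  # constant shift up to fp jitter
  if (degenerate) {
    t <- if (m == 0) 0 else sign(m) * Inf
    s <- 0
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- switch(alternative,
    two.sided = if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df),
    less = stats::pt(t, df),
    greater = stats::pt(t, df, lower.tail = FALSE))
  if (s == 0 && m == 0) p <- 1
  list(statistic = t, pValue = p, df = df, meanDiff = m)
}
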