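#' Construct scene backscatter parameters
#'
#' Class-conditional Gaussian dB parameters for the synthetic radar scenes.
#' Defaults give the clear bimodal separation between flooded forest
#' (brighter at HH through the double-bounce mechanism) and terra firme:
#' HH means -6 / -9 dB, HV means -12 / -13 dB, 1 dB noise.
#'
#' @param hhMeanFloodedDb,hhMeanDryDb HH class means (dB); flooded must
#'   exceed dry.
#' @param hvMeanFloodedDb,hvMeanDryDb HV class means (dB).
#' @param noiseSdDb Gaussian per-pixel noise SD (dB, >= 0).
#' @param incidenceRefDeg reference incidence angle (degrees).
#' @param seed integer seed.
#' @return a [SceneParams-class].
#' @export
sceneParams <- function(hhMeanFloodedDb = -6, hhMeanDryDb = -9,
                        hvMeanFloodedDb = -12, hvMeanDryDb = -13,
                        noiseSdDb = 1, incidenceRefDeg = 38.7, seed = 1L) {
  methods::new("SceneParams",
    hhMeanFloodedDb = hhMeanFloodedDb, hhMeanDryDb = hhMeanDryDb,
    hvMeanFloodedDb = hvMeanFloodedDb, hvMeanDryDb = hvMeanDryDb,
    noiseSdDb = noiseSdDb, incidenceRefDeg = incidenceRefDeg,
    seed = as.integer(seed))
}

#' Construct flood dynamics
#'
#' Piecewise-linear trajectory of the HAND cutoff driving the synthetic
#' flood-truth series, with an optional breakpoint (e.g. a drying trend
#' turning into a wetting trend) and independent Bernoulli label noise.
#'
#' @param years strictly increasing integer years.
#' @param baseCutoffM HAND cutoff (m) in the first year.
#' @param trendMPerYear cutoff slope (m/yr) before the breakpoint.
#' @param breakpointYear breakpoint year, or NA for a single trend.
#' @param postBreakTrendMPerYear cutoff slope (m/yr) after the breakpoint.
#' @param noiseFraction label-flip probability in \[0, 1\].
#' @param spatialAnomalySdM SD (m) of a static smooth water-level anomaly
#'   field (see [generateFloodTruth()]); default 0.
#' @param seed integer seed.
#' @return a [FloodDynamics-class].
#' @export
floodDynamics <- function(years, baseCutoffM, trendMPerYear = 0,
                          breakpointYear = NA_integer_,
                          postBreakTrendMPerYear = NA_real_,
                          noiseFraction = 0, spatialAnomalySdM = 0,
                          seed = 1L) {
  methods::new("FloodDynamics",
    years = as.integer(years), baseCutoffM = baseCutoffM,
    trendMPerYear = trendMPerYear,
    breakpointYear = as.integer(breakpointYear),
    postBreakTrendMPerYear = as.numeric(postBreakTrendMPerYear),
    noiseFraction = noiseFraction,
    spatialAnomalySdM = spatialAnomalySdM, seed = as.integer(seed))
}

# Per-year HAND cutoffs implied by a FloodDynamics: linear in year up to the
# breakpoint, then continuing from the breakpoint value at the post slope.
floodCutoffs <- function(dynamics) {
  y0 <- dynamics@years[1L]
  bp <- dynamics@breakpointYear
  vapply(dynamics@years, function(y) {
    if (is.na(bp) || y <= bp) {
      dynamics@baseCutoffM + dynamics@trendMPerYear * (y - y0)
    } else {
      atBp <- dynamics@baseCutoffM + dynamics@trendMPerYear * (bp - y0)
      atBp + dynamics@postBreakTrendMPerYear * (y - bp)
    }
  }, numeric(1))
}

#' Generate the per-year flood-truth series
#'
#' For each year, forest pixels with HAND at or below that year's effective
#' cutoff are flooded; labels are then flipped independently with
#' probability \code{noiseFraction} (forest pixels only). When
#' \code{spatialAnomalySdM > 0} the cutoff varies smoothly in space around
#' its annual value (one static anomaly field drawn per series), emulating
#' sub-grid hydrological heterogeneity: flooding is then correlated with,
#' but not determined by, HAND — including occasional flood patches at
#' higher HAND — while the backscatter signal still reflects the actual
#' water surface. Every year must contain at least one flooded and one dry
#' forest pixel before noise, otherwise the scene is degenerate and an
#' error is raised.
#'
#' @param terrain a [TerrainModel-class].
#' @param dynamics a [FloodDynamics-class].
#' @return named list (by year) of logical truth grids.
#' @examples
#' tm <- generateTerrain(16, 16, seed = 3)
#' dyn <- floodDynamics(2007:2009, baseCutoffM = 1, trendMPerYear = 0.2)
#' truth <- generateFloodTruth(tm, dyn)
#' sapply(truth, sum)
#' @export
generateFloodTruth <- function(terrain, dynamics) {
  stopifnot(methods::is(terrain, "TerrainModel"),
            methods::is(dynamics, "FloodDynamics"))
  cutoffs <- floodCutoffs(dynamics)
  hand <- terrain@handM
  forest <- terrain@forestMask
  withSeed(dynamics@seed, {
    anomaly <- 0
    if (dynamics@spatialAnomalySdM > 0) {
      f <- smoothField(nrow(hand), ncol(hand))
      f <- f - mean(f)
      anomaly <- f * dynamics@spatialAnomalySdM / stats::sd(f)
    }
    out <- lapply(seq_along(dynamics@years), function(i) {
      flooded <- forest & hand <= cutoffs[i] + anomaly
      if (!any(flooded[forest]) || all(flooded[forest]))
        .stopf("degenerate scene in year %d: cutoff %.3f m leaves a single class",
               dynamics@years[i], cutoffs[i])
      if (dynamics@noiseFraction > 0) {
        flip <- forest & matrix(stats::runif(length(hand)) < dynamics@noiseFraction,
                                nrow(hand), ncol(hand))
        flooded <- xor(flooded, flip)
      }
      flooded
    })
    names(out) <- as.character(dynamics@years)
    out
  })
}

#' Generate a synthetic backscatter scene
#'
#' Draws HH and HV gamma-naught values (dB) around the class means given by
#' \code{params}, conditioned on the flood-truth grid, with independent
#' Gaussian dB noise. The incidence-angle grid is populated at the reference
#' angle and all quality flags are good (0) unless \code{gapMask} marks
#' pixels to be flagged bad (flag 1), emulating layover/shadow or mosaic
#' gaps. Deterministic for a fixed \code{params@seed} and year.
#'
#' @param terrain a [TerrainModel-class] (defines the grid).
#' @param floodTruth logical truth grid conformable with the terrain.
#' @param params a [SceneParams-class].
#' @param year integer acquisition year (participates in the noise seed so
#'   different years get independent speckle).
#' @param gapMask optional logical grid of pixels to flag as bad quality.
#' @return a [BackscatterScene-class].
#' @export
generateBackscatter <- function(terrain, floodTruth, params, year,
                                gapMask = NULL) {
  stopifnot(methods::is(terrain, "TerrainModel"),
            methods::is(params, "SceneParams"))
  hand <- terrain@handM
  if (!identical(dim(floodTruth), dim(hand)))
    .stopf("floodTruth shape %s does not match terrain %s",
           paste(dim(floodTruth), collapse = "x"),
           paste(dim(hand), collapse = "x"))
  nr <- nrow(hand); nc <- ncol(hand)
  withSeed(childSeed(params@seed, year), {
    hh <- ifelse(floodTruth, params@hhMeanFloodedDb, params@hhMeanDryDb) +
      stats::rnorm(nr * nc, sd = params@noiseSdDb)
    hv <- ifelse(floodTruth, params@hvMeanFloodedDb, params@hvMeanDryDb) +
      stats::rnorm(nr * nc, sd = params@noiseSdDb)
    flags <- matrix(0L, nr, nc)
    if (!is.null(gapMask)) {
      if (!identical(dim(gapMask), dim(hand)))
        .stopf("gapMask shape does not match terrain")
      flags[gapMask] <- 1L
    }
    methods::new("BackscatterScene",
      year = as.integer(year),
      hhDb = matrix(hh, nr, nc), hvDb = matrix(hv, nr, nc),
      incidenceDeg = matrix(params@incidenceRefDeg, nr, nc),
      qualityFlags = flags,
      validMask = matrix(TRUE, nr, nc),
      filledMask = matrix(FALSE, nr, nc))
  })
}

#' Sample labelled ground-truth points from a truth grid
#'
#' Draws reference points whose labels agree with the flood-truth grid at
#' their pixel locations, using proportional stratified allocation so both
#' classes are always represented. The default number of points is 1087,
#' matching the size of the GPS campaign dataset the classifier is designed
#' around.
#'
#' @param floodTruth logical truth grid (TRUE = swamp).
#' @param nPoints number of points (>= 2; must not exceed eligible pixels).
#' @param seed integer seed.
#' @param eligibleMask optional logical grid restricting candidate pixels
#'   (typically the forest mask); defaults to all pixels.
#' @return a [GroundTruthSet-class].
#' @examples
#' tm <- generateTerrain(48, 48, seed = 2)
#' truth <- forestMask(tm) & handGrid(tm) <= 1
#' gt <- generateGroundTruth(truth, nPoints = 20, seed = 1,
#'                           eligibleMask = forestMask(tm))
#' nrow(groundTruthPoints(gt))
#' @export
generateGroundTruth <- function(floodTruth, nPoints = 1087L, seed = 1L,
                                eligibleMask = NULL) {
  if (is.null(eligibleMask))
    eligibleMask <- matrix(TRUE, nrow(floodTruth), ncol(floodTruth))
  if (nPoints < 2L) .stopf("nPoints must be >= 2")
  swampIdx <- which(eligibleMask & floodTruth)
  dryIdx <- which(eligibleMask & !floodTruth)
  if (length(swampIdx) == 0L || length(dryIdx) == 0L)
    .stopf("both classes must be present among eligible pixels")
  if (nPoints > length(swampIdx) + length(dryIdx))
    .stopf("nPoints (%d) exceeds the %d eligible pixels", nPoints,
           length(swampIdx) + length(dryIdx))
  prev <- length(swampIdx) / (length(swampIdx) + length(dryIdx))
  nSwamp <- round(nPoints * prev)
  nSwamp <- min(max(nSwamp, 1L), nPoints - 1L, length(swampIdx))
  nDry <- nPoints - nSwamp
  if (nDry > length(dryIdx)) {
    nDry <- length(dryIdx)
    nSwamp <- nPoints - nDry
  }
  withSeed(seed, {
    pick <- c(sample(swampIdx, nSwamp), sample(dryIdx, nDry))
    lab <- factor(rep(c("swamp", "terra_firme"), c(nSwamp, nDry)),
                  levels = c("swamp", "terra_firme"))
    nr <- nrow(floodTruth)
    pts <- data.frame(
      row = ((pick - 1L) %% nr) + 1L,
      col = ((pick - 1L) %/% nr) + 1L,
      label = lab)
    methods::new("GroundTruthSet", points = pts,
                 gridDim = c(nrow(floodTruth), ncol(floodTruth)))
  })
}

#' Generate an annual EVI stack with imposed trends
#'
#' Per-pixel enhanced-vegetation-index series built as a stratum baseline
#' plus a linear trend in year plus Gaussian noise, with observations dropped
#' independently at \code{missingFraction}. Strata follow flood frequency
#' across the truth series: pixels flooded every year are swamp (baseline
#' 0.45 by default), pixels never flooded are terra firme (0.50); pixels of
#' intermediate frequency take the midpoint baseline. The swamp baseline sits
#' below the terra firme baseline, encoding lower swamp productivity.
#'
#' @param terrain a [TerrainModel-class].
#' @param floodTruthSeries named list of truth grids (from
#'   [generateFloodTruth()]).
#' @param trendPerYear EVI trend (units/yr); either one scalar for all
#'   pixels or a named vector with entries \code{swamp} and
#'   \code{terra_firme} (intermediate pixels get the mean of the two).
#' @param noiseSd Gaussian noise SD (EVI units).
#' @param missingFraction probability an observation is missing, in \[0, 1).
#' @param seed integer seed.
#' @param baselineSwamp,baselineTerraFirme stratum baselines.
#' @return list with \code{years}, \code{evi} (list of matrices, NA where
#'   missing or non-forest), \code{available} (list of logical matrices),
#'   \code{floodFrequency} (integer grid), \code{nMaps}.
#' @export
generateEviStack <- function(terrain, floodTruthSeries, trendPerYear = 0,
                             noiseSd = 0, missingFraction = 0, seed = 1L,
                             baselineSwamp = 0.45, baselineTerraFirme = 0.50) {
  if (missingFraction < 0 || missingFraction >= 1)
    .stopf("missingFraction must be in [0, 1)")
  years <- as.integer(names(floodTruthSeries))
  nMaps <- length(floodTruthSeries)
  freq <- Reduce(`+`, lapply(floodTruthSeries, function(m) m + 0L))
  forest <- terrain@forestMask
  nr <- nrow(forest); nc <- ncol(forest)

  if (length(trendPerYear) == 1L && is.null(names(trendPerYear))) {
    trSwamp <- trTf <- as.numeric(trendPerYear)
  } else {
    trSwamp <- as.numeric(trendPerYear[["swamp"]])
    trTf <- as.numeric(trendPerYear[["terra_firme"]])
  }
  base <- matrix(0.5 * (baselineSwamp + baselineTerraFirme), nr, nc)
  base[freq == nMaps] <- baselineSwamp
  base[freq == 0L] <- baselineTerraFirme
  trend <- matrix(0.5 * (trSwamp + trTf), nr, nc)
  trend[freq == nMaps] <- trSwamp
  trend[freq == 0L] <- trTf

  withSeed(seed, {
    evi <- vector("list", nMaps)
    avail <- vector("list", nMaps)
    for (i in seq_len(nMaps)) {
      v <- base + trend * (years[i] - years[1L]) +
        stats::rnorm(nr * nc, sd = noiseSd)
      a <- matrix(stats::runif(nr * nc) >= missingFraction, nr, nc)
      v[!a | !forest] <- NA_real_
      evi[[i]] <- matrix(v, nr, nc)
      avail[[i]] <- a & forest
    }
    names(evi) <- names(avail) <- as.character(years)
    list(years = years, evi = evi, available = avail,
         floodFrequency = freq, nMaps = nMaps)
  })
}
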