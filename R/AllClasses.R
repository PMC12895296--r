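#' @import methods
NULL

#' Canonical water-table-level class labels and breaks
#'
#' The six water-table-level (WTL) classes used throughout the package, in
#' order from driest to wettest: below-ground levels of 70 cm or more
#' (\code{"<= -70 cm"}) up to standing water deeper than 40 cm
#' (\code{"> 40 cm"}). Binning is lower-exclusive / upper-inclusive, with the
#' lowest class closed below at minus infinity, so a value exactly on a
#' boundary is assigned to the lower-labelled class (e.g. -70 cm falls in
#' \code{"<= -70 cm"}).
#'
#' @return \code{wtlClassLabels} returns a character vector of length 6;
#'   \code{wtlClassBreaks} returns the 7 bin edges in cm
#'   (\code{-Inf, -70, -50, -30, -5, 40, Inf}).
#' @examples
#' wtlClassLabels()
#' wtlClassBreaks()
#' @export
wtlClassLabels <- function() {
  c("<= -70 cm", "-70 to -50 cm", "-50 to -30 cm",
    "-30 to -5 cm", "-5 to 40 cm", "> 40 cm")
}

#' @rdname wtlClassLabels
#' @export
wtlClassBreaks <- function() {
  c(-Inf, -70, -50, -30, -5, 40, Inf)
}

.checkConformable <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1L]]
  for (d in dims) {
    if (is.null(d) || length(d) != 2L || !identical(d, ref))
      return("all grids must be 2D and share one shape")
  }
  TRUE
}

#' TerrainModel: the hydrological substrate
#'
#' Holds a Height Above Nearest Drainage (HAND) grid together with a forest
#' mask and a drainage mask on a common raster. HAND measures how high each
#' pixel sits above the nearest drainage channel; it is zero on every
#' watercourse pixel and non-negative everywhere.
#'
#' @slot handM numeric matrix, HAND in metres (>= 0; exactly 0 on drainage).
#' @slot forestMask logical matrix, TRUE where forested.
#' @slot drainageMask logical matrix, TRUE on drainage channels.
#' @slot pixelSizeM numeric(1), pixel edge length in metres (> 0).
#' @seealso [generateTerrain()]
#' @export
setClass("TerrainModel",
  representation(
    handM = "matrix",
    forestMask = "matrix",
    drainageMask = "matrix",
    pixelSizeM = "numeric"
  )
)

setValidity("TerrainModel", function(object) {
  msg <- .checkConformable(object@handM, object@forestMask, object@drainageMask)
  if (!isTRUE(msg)) return(msg)
  if (!is.logical(object@forestMask) || !is.logical(object@drainageMask))
    return("forestMask and drainageMask must be logical")
  if (length(object@pixelSizeM) != 1L || !is.finite(object@pixelSizeM) ||
      object@pixelSizeM <= 0)
    return("pixelSizeM must be a single positive number")
  if (any(object@handM < 0, na.rm = TRUE))
    return("handM must be non-negative everywhere")
  if (any(object@handM[object@drainageMask] != 0))
    return("handM must be exactly 0 on every drainage pixel")
  TRUE
})

#' SceneParams: class-conditional backscatter distribution parameters
#'
#' Gaussian dB-domain emulation of the bimodal separation between flooded and
#' non-flooded forest backscatter. The double-bounce mechanism makes flooded
#' forest brighter at HH, so the flooded HH mean must exceed the dry HH mean.
#'
#' @slot hhMeanFloodedDb,hhMeanDryDb HH gamma-naught class means (dB).
#' @slot hvMeanFloodedDb,hvMeanDryDb HV gamma-naught class means (dB).
#' @slot noiseSdDb per-pixel Gaussian noise SD (dB, >= 0).
#' @slot incidenceRefDeg reference incidence angle (degrees).
#' @slot seed integer random seed.
#' @seealso [sceneParams()], [generateBackscatter()]
#' @export
setClass("SceneParams",
  representation(
    hhMeanFloodedDb = "numeric", hhMeanDryDb = "numeric",
    hvMeanFloodedDb = "numeric", hvMeanDryDb = "numeric",
    noiseSdDb = "numeric", incidenceRefDeg = "numeric", seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  if (object@noiseSdDb < 0) return("noiseSdDb must be >= 0")
  if (object@hhMeanFloodedDb <= object@hhMeanDryDb)
    return("flooded HH mean must exceed dry HH mean (double-bounce convention)")
  if (object@incidenceRefDeg <= 0 || object@incidenceRefDeg >= 90)
    return("incidenceRefDeg must be in (0, 90)")
  TRUE
})

#' FloodDynamics: multi-year inundation dynamics
#'
#' Defines a piecewise-linear trajectory for the HAND cutoff that controls
#' which forest pixels are flooded each year, optionally with a breakpoint
#' separating a pre-break trend from a post-break trend (e.g. a
#' drying-then-wetting shift), plus independent Bernoulli label noise.
#'
#' @slot years strictly increasing integer vector of observation years.
#' @slot baseCutoffM HAND cutoff (m) in the first year.
#' @slot trendMPerYear cutoff change per year before the breakpoint.
#' @slot breakpointYear integer(1) or NA for a single linear trend.
#' @slot postBreakTrendMPerYear cutoff change per year after the breakpoint.
#' @slot noiseFraction Bernoulli label-flip probability in \[0, 1\].
#' @slot spatialAnomalySdM standard deviation (m) of a static smooth
#'   water-level anomaly field added to the cutoff, emulating sub-grid
#'   hydrological heterogeneity (0 = flooding strictly thresholded on HAND).
#' @slot seed integer random seed.
#' @seealso [floodDynamics()], [generateFloodTruth()]
#' @export
setClass("FloodDynamics",
  representation(
    years = "integer", baseCutoffM = "numeric", trendMPerYear = "numeric",
    breakpointYear = "integer", postBreakTrendMPerYear = "numeric",
    noiseFraction = "numeric", spatialAnomalySdM = "numeric", seed = "integer"
  )
)

setValidity("FloodDynamics", function(object) {
  if (length(object@years) < 1L || is.unsorted(object@years, strictly = TRUE))
    return("years must be strictly increasing")
  if (object@noiseFraction < 0 || object@noiseFraction > 1)
    return("noiseFraction must be in [0, 1]")
  if (object@spatialAnomalySdM < 0)
    return("spatialAnomalySdM must be >= 0")
  TRUE
})

#' BackscatterScene: analysis-ready dual-polarisation radar scene
#'
#' One year of HH/HV gamma-naught backscatter in dB with the local incidence
#' angle, per-pixel data-quality flags, a validity mask, and a record of which
#' pixels were gap-filled from a donor year. dB values are finite wherever
#' the valid mask is TRUE.
#'
#' @slot year integer acquisition year.
#' @slot hhDb,hvDb numeric matrices, gamma naught (dB).
#' @slot incidenceDeg numeric matrix, local incidence angle (degrees).
#' @slot qualityFlags integer matrix (0 = good by convention).
#' @slot validMask logical matrix.
#' @slot filledMask logical matrix, TRUE where values came from a donor scene.
#' @seealso [generateBackscatter()], [applyQualityMask()], [fillGaps()]
#' @export
setClass("BackscatterScene",
  representation(
    year = "integer",
    hhDb = "matrix", hvDb = "matrix",
    incidenceDeg = "matrix", qualityFlags = "matrix",
    validMask = "matrix", filledMask = "matrix"
  )
)

setValidity("BackscatterScene", function(object) {
  msg <- .checkConformable(object@hhDb, object@hvDb, object@incidenceDeg,
                           object@qualityFlags, object@validMask,
                           object@filledMask)
  if (!isTRUE(msg)) return(msg)
  if (!is.logical(object@validMask) || !is.logical(object@filledMask))
    return("validMask and filledMask must be logical")
  v <- object@validMask
  if (any(!is.finite(object@hhDb[v])) || any(!is.finite(object@hvDb[v])))
    return("dB values must be finite wherever validMask is TRUE")
  TRUE
})

#' GroundTruthSet: labelled reference points
#'
#' GPS-style reference points with binary labels: permanently flooded
#' (peat-forming) swamp forest vs terra firme forest.
#'
#' @slot points data.frame with columns \code{row}, \code{col} (1-based pixel
#'   indices) and \code{label} (factor with levels \code{swamp},
#'   \code{terra_firme}).
#' @slot gridDim integer(2), dimensions of the grid the points index into.
#' @seealso [generateGroundTruth()]
#' @export
setClass("GroundTruthSet",
  representation(points = "data.frame", gridDim = "integer")
)

setValidity("GroundTruthSet", function(object) {
  p <- object@points
  if (!all(c("row", "col", "label") %in% names(p)))
    return("points needs columns row, col, label")
  if (!is.factor(p$label) ||
      !identical(levels(p$label), c("swamp", "terra_firme")))
    return("label must be a factor with levels swamp, terra_firme")
  if (length(object@gridDim) != 2L)
    return("gridDim must be length 2")
  if (nrow(p) > 0 &&
      (any(p$row < 1 | p$row > object@gridDim[1L]) ||
       any(p$col < 1 | p$col > object@gridDim[2L])))
    return("point coordinates must lie inside grid bounds")
  TRUE
})

#' FloodMap: one year of binary inundation
#'
#' @slot year integer.
#' @slot flooded logical matrix; TRUE = swamp (inundated) forest.
#' @slot analysisMask logical matrix; the flood-potential domain actually
#'   classified (flooded is always a subset of it).
#' @slot pixelSizeM numeric(1), metres.
#' @seealso [classifyYear()], [extentSeries()]
#' @export
setClass("FloodMap",
  representation(
    year = "integer", flooded = "matrix", analysisMask = "matrix",
    pixelSizeM = "numeric"
  )
)

setValidity("FloodMap", function(object) {
  msg <- .checkConformable(object@flooded, object@analysisMask)
  if (!isTRUE(msg)) return(msg)
  if (!is.logical(object@flooded) || !is.logical(object@analysisMask))
    return("flooded and analysisMask must be logical")
  if (any(object@flooded & !object@analysisMask))
    return("flooded pixels must lie inside analysisMask")
  if (object@pixelSizeM <= 0) return("pixelSizeM must be positive")
  TRUE
})

#' AccuracyReport: confusion matrix and derived accuracies
#'
#' Confusion counts from held-out validation points, with rows = mapped
#' (predicted) class and columns = reference class. Overall accuracy is the
#' trace over the total; user accuracy of a class is its diagonal count over
#' its row sum (complement of commission error); producer accuracy is the
#' diagonal over the column sum (complement of omission error).
#'
#' @slot confusion 2x2 integer matrix (rows = mapped, cols = reference).
#' @slot overall numeric(1) in \[0, 1\].
#' @slot userAccuracy,producerAccuracy named numeric(2).
#' @seealso [trainFloodClassifier()], [errorAdjustedExtent()]
#' @export
setClass("AccuracyReport",
  representation(
    confusion = "matrix", overall = "numeric",
    userAccuracy = "numeric", producerAccuracy = "numeric"
  )
)

setValidity("AccuracyReport", function(object) {
  cm <- object@confusion
  if (!identical(dim(cm), c(2L, 2L))) return("confusion must be 2x2")
  tot <- sum(cm)
  if (tot <= 0) return("confusion must contain counts")
  if (abs(object@overall - sum(diag(cm)) / tot) > 1e-12)
    return("overall must equal trace/total")
  TRUE
})

#' FloodClassifier: trained random-forest flood classifier
#'
#' Wraps the fitted random forest (500 trees by default) over the feature
#' space (HH, HV, HV-HH ratio in dB, HAND), together with the accuracy report
#' computed on the held-out validation fraction.
#'
#' @slot model the fitted \code{randomForest} object.
#' @slot report an [AccuracyReport-class].
#' @slot featureNames character vector of feature column names.
#' @slot nTrain,nHoldout integer counts of split sizes.
#' @seealso [trainFloodClassifier()], [classifyYear()]
#' @export
setClass("FloodClassifier",
  representation(
    model = "ANY", report = "AccuracyReport",
    featureNames = "character", nTrain = "integer", nHoldout = "integer"
  )
)

#' WaterTableGrid: signed per-pixel water-table level
#'
#' Water-table level (WTL) in cm relative to the ground surface: positive on
#' flooded pixels (standing-water depth obtained by inverting HAND against
#' the year's 90th-percentile flooded HAND), negative on non-flooded pixels
#' inside the maximum flood extent (depth below ground relative to the
#' 10th-percentile non-flooded HAND, clamped to at most -5 cm). Undefined
#' (NA) outside the domain mask.
#'
#' @slot year integer.
#' @slot wtlCm numeric matrix (cm; NA outside domainMask).
#' @slot domainMask logical matrix, the maximum flood extent analysed.
#' @slot floodedMask logical matrix, pixels flooded that year.
#' @slot referenceMaxHandM numeric(1), the percentile-based flooded HAND
#'   reference (m) used for depth inversion.
#' @slot referenceMinHandM numeric(1), the percentile-based non-flooded HAND
#'   reference (m) used for below-ground levels (NA if the year is fully
#'   flooded).
#' @slot pixelSizeM numeric(1), metres.
#' @seealso [waterTable()], [wtlClassAreas()]
#' @export
setClass("WaterTableGrid",
  representation(
    year = "integer", wtlCm = "matrix",
    domainMask = "matrix", floodedMask = "matrix",
    referenceMaxHandM = "numeric", referenceMinHandM = "numeric",
    pixelSizeM = "numeric"
  )
)

setValidity("WaterTableGrid", function(object) {
  msg <- .checkConformable(object@wtlCm, object@domainMask, object@floodedMask)
  if (!isTRUE(msg)) return(msg)
  w <- object@wtlCm
  if (any(!is.na(w) & !object@domainMask))
    return("wtlCm must be NA outside domainMask")
  fl <- object@floodedMask & object@domainMask
  if (any(w[fl] < 0, na.rm = TRUE))
    return("wtlCm must be >= 0 on flooded pixels")
  dry <- object@domainMask & !object@floodedMask
  if (any(w[dry] > -5, na.rm = TRUE))
    return("wtlCm must be <= -5 cm on non-flooded domain pixels")
  TRUE
})

#' FluxTable: per-WTL-class greenhouse-gas flux densities
#'
#' A tidy table of net flux densities (tonnes km^-2 yr^-1) for CO2, CH4 and
#' N2O in each of the six water-table-level classes, with 95% confidence
#' bounds. Negative densities (sinks) are allowed. Exactly the six canonical
#' classes (see [wtlClassLabels()]) must be present for every gas.
#'
#' @slot table data.frame with columns \code{class}, \code{gas}, \code{mean},
#'   \code{ciLow}, \code{ciHigh}, \code{units}.
#' @seealso [defaultFluxTable()], [fluxTable()], [annualEmissions()]
#' @export
setClass("FluxTable", representation(table = "data.frame"))

setValidity("FluxTable", function(object) {
  tb <- object@table
  need <- c("class", "gas", "mean", "ciLow", "ciHigh")
  if (!all(need %in% names(tb)))
    return("table needs columns class, gas, mean, ciLow, ciHigh")
  if (!setequal(unique(tb$class), wtlClassLabels()))
    return("table must contain exactly the six canonical WTL classes")
  if (!setequal(unique(tb$gas), c("CO2", "CH4", "N2O")))
    return("table must contain gases CO2, CH4, N2O")
  if (nrow(tb) != 18L)
    return("table must have one row per class x gas (18 rows)")
  if (any(tb$ciLow > tb$mean | tb$mean > tb$ciHigh))
    return("each row must satisfy ciLow <= mean <= ciHigh")
  TRUE
})

#' GwpWeights: global-warming-potential weight set
#'
#' CO2-equivalent weights for CH4 and N2O at a fixed time horizon:
#' 34 and 298 over 100 years, 82.5 and 273 over 20 years.
#'
#' @slot horizon \code{"100yr"} or \code{"20yr"}.
#' @slot wCh4,wN2o numeric(1) weights.
#' @seealso [gwpWeights()], [co2Equivalent()]
#' @export
setClass("GwpWeights",
  representation(horizon = "character", wCh4 = "numeric", wN2o = "numeric")
)

setValidity("GwpWeights", function(object) {
  ok <- switch(object@horizon,
    "100yr" = object@wCh4 == 34 && object@wN2o == 298,
    "20yr"  = object@wCh4 == 82.5 && object@wN2o == 273,
    FALSE)
  if (!isTRUE(ok))
    return("horizon must be '100yr' (34, 298) or '20yr' (82.5, 273)")
  TRUE
})

#' TrendFit: ordinary-least-squares trend
#'
#' Slope, intercept, two-sided 95% confidence interval and p-value (t
#' distribution, n - 2 df) from an OLS fit of a series on year.
#'
#' @slot slope,intercept numeric(1).
#' @slot slopeCiLow,slopeCiHigh numeric(1), 95% CI bounds on the slope.
#' @slot pValue numeric(1).
#' @slot n integer(1), number of observations used.
#' @seealso [olsTrend()]
#' @export
setClass("TrendFit",
  representation(
    slope = "numeric", intercept = "numeric",
    slopeCiLow = "numeric", slopeCiHigh = "numeric",
    pValue = "numeric", n = "integer"
  )
)

setValidity("TrendFit", function(object) {
  if (object@n < 3L) return("n must be >= 3")
  if (object@slopeCiLow > object@slope + 1e-12 ||
      object@slopeCiHigh < object@slope - 1e-12)
    return("CI must bracket the slope")
  TRUE
})

#' PiecewiseFit: continuous one-breakpoint segmented trend
#'
#' Two-segment linear fit, continuous at the breakpoint, with the breakpoint
#' chosen by exhaustive search over interior observed years minimising the
#' residual sum of squares (ties broken toward the earliest year).
#'
#' @slot breakpointYear integer(1), strictly inside the year range.
#' @slot slopePre,slopePost numeric(1), segment slopes (units/yr).
#' @slot intercept numeric(1), value model intercept at year 0.
#' @slot rss numeric(1); never exceeds the single-line RSS.
#' @slot n integer(1).
#' @seealso [piecewiseTrend()]
#' @export
setClass("PiecewiseFit",
  representation(
    breakpointYear = "integer", slopePre = "numeric", slopePost = "numeric",
    intercept = "numeric", rss = "numeric", n = "integer"
  )
)
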