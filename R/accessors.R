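#' @rdname accessors
#' @export
setMethod("handGrid", "TerrainModel", function(object) object@handM)

#' @rdname accessors
#' @export
setMethod("forestMask", "TerrainModel", function(object) object@forestMask)

#' @rdname accessors
#' @export
setMethod("drainageMask", "TerrainModel", function(object) object@drainageMask)

#' @rdname accessors
#' @export
setMethod("pixelSize", "TerrainModel", function(object) object@pixelSizeM)

#' @rdname accessors
#' @export
setMethod("pixelSize", "FloodMap", function(object) object@pixelSizeM)

#' @rdname accessors
#' @export
setMethod("pixelSize", "WaterTableGrid", function(object) object@pixelSizeM)

#' @rdname accessors
#' @export
setMethod("sceneYear", "BackscatterScene", function(object) object@year)

#' @rdname accessors
#' @export
setMethod("sceneYear", "FloodMap", function(object) object@year)

#' @rdname accessors
#' @export
setMethod("sceneYear", "WaterTableGrid", function(object) object@year)

#' @rdname accessors
#' @export
setMethod("hhGrid", "BackscatterScene", function(object) object@hhDb)

#' @rdname accessors
#' @export
setMethod("hvGrid", "BackscatterScene", function(object) object@hvDb)

#' @rdname accessors
#' @export
setMethod("validMask", "BackscatterScene", function(object) object@validMask)

#' @rdname accessors
#' @export
setMethod("filledMask", "BackscatterScene", function(object) object@filledMask)

#' @rdname accessors
#' @export
setMethod("floodedMask", "FloodMap", function(object) object@flooded)

#' @rdname accessors
#' @export
setMethod("floodedMask", "WaterTableGrid", function(object) object@floodedMask)

#' @rdname accessors
#' @export
setMethod("analysisMask", "FloodMap", function(object) object@analysisMask)

#' @rdname accessors
#' @export
setMethod("analysisMask", "WaterTableGrid", function(object) object@domainMask)

#' @rdname accessors
#' @export
setMethod("groundTruthPoints", "GroundTruthSet", function(object) object@points)

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "AccuracyReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setMethod("overallAccuracy", "AccuracyReport", function(object) object@overall)

#' @rdname accessors
#' @export
setMethod("accuracyReport", "FloodClassifier", function(object) object@report)

#' @rdname accessors
#' @export
setMethod("wtlGrid", "WaterTableGrid", function(object) object@wtlCm)

#' @rdname accessors
#' @export
setMethod("fluxValues", "FluxTable", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("trendSlope", "TrendFit", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("trendSlope", "PiecewiseFit",
          function(object) c(pre = object@slopePre, post = object@slopePost))

#' @rdname accessors
#' @export
setMethod("trendCi", "TrendFit",
          function(object) c(low = object@slopeCiLow, high = object@slopeCiHigh))

#' @rdname accessors
#' @export
setMethod("trendPValue", "TrendFit", function(object) object@pValue)

#' @rdname accessors
#' @export
setMethod("breakpointYear", "PiecewiseFit", function(object) object@breakpointYear)

setMethod("show", "TerrainModel", function(object) {
  d <- dim(object@handM)
  cat(sprintf("TerrainModel: %d x %d grid at %g m\n", d[1], d[2],
              object@pixelSizeM))
  cat(sprintf("  HAND: 0 - %.2f m | forest: %.1f%% | drainage pixels: %d\n",
              max(object@handM), 100 * mean(object@forestMask),
              sum(object@drainageMask)))
})

setMethod("show", "BackscatterScene", function(object) {
  d <- dim(object@hhDb)
  cat(sprintf("BackscatterScene (%d): %d x %d | valid %.1f%% | filled %d px\n",
              object@year, d[1], d[2], 100 * mean(object@validMask),
              sum(object@filledMask)))
})

setMethod("show", "FloodMap", function(object) {
  cat(sprintf("FloodMap (%d): %d flooded px of %d in mask (%.4f km2)\n",
              object@year, sum(object@flooded), sum(object@analysisMask),
              sum(object@flooded) * object@pixelSizeM^2 / 1e6))
})

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf("AccuracyReport: overall %.3f\n", object@overall))
  print(object@confusion)
  cat("  user accuracy:     ",
      paste(sprintf("%s %.3f", names(object@userAccuracy),
                    object@userAccuracy), collapse = " | "), "\n")
  cat("  producer accuracy: ",
      paste(sprintf("%s %.3f", names(object@producerAccuracy),
                    object@producerAccuracy), collapse = " | "), "\n")
})

setMethod("show", "FloodClassifier", function(object) {
  cat(sprintf("FloodClassifier: %d trees on features (%s); train n=%d, holdout n=%d\n",
              object@model$ntree, paste(object@featureNames, collapse = ", "),
              object@nTrain, object@nHoldout))
  cat(sprintf("  holdout overall accuracy: %.3f\n", object@report@overall))
})

setMethod("show", "WaterTableGrid", function(object) {
  w <- object@wtlCm
  cat(sprintf("WaterTableGrid (%d): domain %d px | flooded %d px | WTL %.0f to %.0f cm\n",
              object@year, sum(object@domainMask), sum(object@floodedMask),
              min(w, na.rm = TRUE), max(w, na.rm = TRUE)))
  cat(sprintf("  HAND references: max %.3f m (flooded), min %s m (non-flooded)\n",
              object@referenceMaxHandM,
              ifelse(is.na(object@referenceMinHandM), "NA",
                     sprintf("%.3f", object@referenceMinHandM))))
})

setMethod("show", "FluxTable", function(object) {
  cat("FluxTable: per-WTL-class net flux densities (t km-2 yr-1)\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "GwpWeights", function(object) {
  cat(sprintf("GwpWeights (%s horizon): CH4 x %g, N2O x %g\n",
              object@horizon, object@wCh4, object@wN2o))
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("TrendFit: slope %.6g /yr (95%% CI %.6g to %.6g), p = %.3g, n = %d\n",
              object@slope, object@slopeCiLow, object@slopeCiHigh,
              object@pValue, object@n))
})

setMethod("show", "PiecewiseFit", function(object) {
  cat(sprintf("PiecewiseFit: breakpoint %d | slopes %.6g -> %.6g /yr | RSS %.6g | n = %d\n",
              object@breakpointYear, object@slopePre, object@slopePost,
              object@rss, object@n))
})

setMethod("show", "GroundTruthSet", function(object) {
  tab <- table(object@points$label)
  cat(sprintf("GroundTruthSet: %d points (%s)\n", nrow(object@points),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})
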