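#' Accessor generics
#'
#' Accessors for the grid-bearing S4 containers. Prefer these over direct
#' slot access.
#'
#' @param object an S4 object from this package.
#' @return The slot value; see the class documentation for types and units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("handGrid", function(object) standardGeneric("handGrid"))

#' @rdname accessors
#' @export
setGeneric("forestMask", function(object) standardGeneric("forestMask"))

#' @rdname accessors
#' @export
setGeneric("drainageMask", function(object) standardGeneric("drainageMask"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sceneYear", function(object) standardGeneric("sceneYear"))

#' @rdname accessors
#' @export
setGeneric("hhGrid", function(object) standardGeneric("hhGrid"))

#' @rdname accessors
#' @export
setGeneric("hvGrid", function(object) standardGeneric("hvGrid"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("filledMask", function(object) standardGeneric("filledMask"))

#' @rdname accessors
#' @export
setGeneric("floodedMask", function(object) standardGeneric("floodedMask"))

#' @rdname accessors
#' @export
setGeneric("analysisMask", function(object) standardGeneric("analysisMask"))

#' @rdname accessors
#' @export
setGeneric("groundTruthPoints", function(object) standardGeneric("groundTruthPoints"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(object) standardGeneric("overallAccuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracyReport", function(object) standardGeneric("accuracyReport"))

#' @rdname accessors
#' @export
setGeneric("wtlGrid", function(object) standardGeneric("wtlGrid"))

#' @rdname accessors
#' @export
setGeneric("fluxValues", function(object) standardGeneric("fluxValues"))

#' @rdname accessors
#' @export
setGeneric("trendSlope", function(object) standardGeneric("trendSlope"))

#' @rdname accessors
#' @export
setGeneric("trendCi", function(object) standardGeneric("trendCi"))

#' @rdname accessors
#' @export
setGeneric("trendPValue", function(object) standardGeneric("trendPValue"))

#' @rdname accessors
#' @export
setGeneric("breakpointYear", function(object) standardGeneric("breakpointYear"))
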