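#' Maximum flood extent across years
#'
#' Union of the flooded pixels over all annual flood maps; the domain inside
#' which water-table levels are reconstructed.
#'
#' @param maps list of [FloodMap-class] objects on one grid.
#' @return logical matrix.
#' @export
maxFloodExtent <- function(maps) {
  if (length(maps) == 0L) .stopf("maps must be non-empty")
  Reduce(`|`, lapply(maps, function(m) m@flooded))
}

#' Standing-water depth over flooded pixels
#'
#' Inverts HAND against a high-percentile reference: the year's maximum
#' water-surface height is taken as the \code{pct}-th percentile (default
#' 90) of HAND over that year's flooded pixels — a robust maximum that
#' discounts isolated flood patches at unrepresentatively high HAND. Depth
#' in cm is \code{100 * (hMax - hand)}; flooded pixels above the reference
#' are clamped to 0 cm (never negative). Percentiles use linear
#' interpolation between order statistics.
#'
#' @param map a [FloodMap-class] with at least one flooded pixel.
#' @param handM numeric HAND matrix (m).
#' @param pct reference percentile (default 90; 100 uses the exact maximum).
#' @return list: \code{depthCm} (numeric matrix, NA on non-flooded pixels)
#'   and \code{referenceMaxHandM}.
#' @export
floodDepth <- function(map, handM, pct = 90) {
  stopifnot(methods::is(map, "FloodMap"))
  if (!any(map@flooded)) .stopf("flood map for %d has no flooded pixels", map@year)
  hMax <- as.numeric(stats::quantile(handM[map@flooded], pct / 100, type = 7))
  depth <- matrix(NA_real_, nrow(handM), ncol(handM))
  depth[map@flooded] <- pmax(100 * (hMax - handM[map@flooded]), 0)
  list(depthCm = depth, referenceMaxHandM = hMax)
}

#' Below-ground water-table level over non-flooded domain pixels
#'
#' For pixels inside the maximum flood extent that are not flooded in a
#' given year, the water table is taken to sit at the \code{pct}-th
#' percentile (default 10) of HAND over those non-flooded pixels — a robust
#' minimum. The level in cm is \code{-100 * (hand - hMin)}, clamped to at
#' most -5 cm so a classifier-dry pixel can never enter an inundated class.
#'
#' @param map a [FloodMap-class].
#' @param handM numeric HAND matrix (m).
#' @param domain logical maximum-flood-extent grid (see [maxFloodExtent()]).
#' @param pct reference percentile (default 10).
#' @return list: \code{wtlCm} (numeric matrix, NA except on non-flooded
#'   domain pixels) and \code{referenceMinHandM}.
#' @export
belowGroundWtl <- function(map, handM, domain, pct = 10) {
  stopifnot(methods::is(map, "FloodMap"))
  dry <- domain & !map@flooded
  if (!any(dry))
    .stopf("year %d: no non-flooded pixels inside the maximum flood extent",
           map@year)
  hMin <- as.numeric(stats::quantile(handM[dry], pct / 100, type = 7))
  wtl <- matrix(NA_real_, nrow(handM), ncol(handM))
  wtl[dry] <- pmin(-100 * (handM[dry] - hMin), -5)
  list(wtlCm = wtl, referenceMinHandM = hMin)
}

#' Reconstruct the signed water-table grid for one year
#'
#' Combines [floodDepth()] (positive, flooded pixels) and [belowGroundWtl()]
#' (negative, non-flooded pixels inside the maximum flood extent) into one
#' signed [WaterTableGrid-class]. Flooded pixels outside the supplied domain
#' are added to it (the union property guarantees this does not occur when
#' the domain is the maximum extent over a set of maps including this one).
#'
#' @param map a [FloodMap-class].
#' @param handM numeric HAND matrix (m).
#' @param domain logical maximum-flood-extent grid.
#' @param depthPct flooded-HAND reference percentile (default 90).
#' @param wtlPct non-flooded-HAND reference percentile (default 10).
#' @return a [WaterTableGrid-class].
#' @export
waterTable <- function(map, handM, domain, depthPct = 90, wtlPct = 10) {
  domain <- domain | map@flooded
  fd <- floodDepth(map, handM, depthPct)
  dry <- domain & !map@flooded
  if (any(dry)) {
    bg <- belowGroundWtl(map, handM, domain, wtlPct)
    hMin <- bg$referenceMinHandM
  } else {
    bg <- list(wtlCm = matrix(NA_real_, nrow(handM), ncol(handM)))
    hMin <- NA_real_
  }
  wtl <- fd$depthCm
  wtl[dry] <- bg$wtlCm[dry]
  methods::new("WaterTableGrid",
    year = map@year, wtlCm = wtl, domainMask = domain,
    floodedMask = map@flooded,
    referenceMaxHandM = fd$referenceMaxHandM,
    referenceMinHandM = hMin,
    pixelSizeM = map@pixelSizeM)
}

# Scalar-style binning of WTL values (cm) into the six classes:
# lower-exclusive, upper-inclusive, lowest class closed below at -Inf.
binWtl <- function(wtlCm) {
  cut(wtlCm, breaks = wtlClassBreaks(), labels = wtlClassLabels(),
      right = TRUE, include.lowest = TRUE)
}

#' Bin a water-table grid into the six WTL classes
#'
#' Half-open binning (lower-exclusive, upper-inclusive) of every domain
#' pixel into the canonical classes, so a value exactly on a boundary lands
#' in the lower-labelled class (-70 cm is in the "<= -70 cm" class, +40 cm
#' in "-5 to 40 cm"). Class areas partition the domain exactly.
#'
#' @param wtg a [WaterTableGrid-class].
#' @return data.frame with columns \code{year}, \code{class} (the six
#'   canonical labels, in order) and \code{areaKm2}.
#' @export
wtlClassAreas <- function(wtg) {
  stopifnot(methods::is(wtg, "WaterTableGrid"))
  vals <- wtg@wtlCm[wtg@domainMask]
  cls <- binWtl(vals)
  pxArea <- wtg@pixelSizeM^2 / 1e6
  counts <- table(cls)
  data.frame(
    year = wtg@year,
    class = wtlClassLabels(),
    areaKm2 = as.numeric(counts[wtlClassLabels()]) * pxArea
  )
}
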