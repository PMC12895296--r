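#' Generate a synthetic terrain model
#'
#' Builds a [TerrainModel-class] whose Height Above Nearest Drainage (HAND)
#' grid has the structure the downstream analysis relies on: drainage
#' channels at HAND = 0, and HAND growing monotonically with grid distance
#' from the nearest channel, plus smooth sub-pixel-scale relief. Channels are
#' meandering random walks spanning the grid from left to right, so each is
#' 8-connected. Because the relief amplitude is strictly below the per-step
#' HAND gain, a pixel strictly farther from drainage (in 8-connected
#' breadth-first steps) always has strictly larger HAND.
#'
#' @param nRows,nCols grid dimensions (each >= 8).
#' @param pixelSizeM pixel edge length in metres (default 25, the L-band
#'   mosaic resolution).
#' @param nChannels number of drainage channels (>= 1).
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param handGainM HAND increase per unit channel distance (m/step).
#' @param reliefFraction smooth-relief amplitude as a fraction of
#'   \code{handGainM}; must be < 1 to preserve distance monotonicity.
#' @param forestFraction approximate fraction of non-drainage pixels that are
#'   forested.
#' @return a [TerrainModel-class].
#' @examples
#' tm <- generateTerrain(16, 16, 25, nChannels = 1, seed = 7)
#' all(handGrid(tm)[drainageMask(tm)] == 0)
#' @export
generateTerrain <- function(nRows, nCols, pixelSizeM = 25, nChannels = 1L,
                            seed = 1L, handGainM = 0.5,
                            reliefFraction = 0.45, forestFraction = 0.9) {
  if (nRows < 8L || nCols < 8L)
    .stopf("nRows and nCols must be >= 8 (got %d x %d)", nRows, nCols)
  if (nChannels < 1L) .stopf("nChannels must be >= 1")
  if (pixelSizeM <= 0) .stopf("pixelSizeM must be positive")
  if (reliefFraction < 0 || reliefFraction >= 1)
    .stopf("reliefFraction must be in [0, 1)")

  withSeed(seed, {
    drainage <- matrix(FALSE, nRows, nCols)
    starts <- sample.int(nRows, nChannels, replace = nChannels > nRows)
    for (ch in seq_len(nChannels)) {
      r <- starts[ch]
      for (cc in seq_len(nCols)) {
        drainage[r, cc] <- TRUE
        r <- min(max(r + sample(c(-1L, 0L, 1L), 1L), 1L), nRows)
      }
    }
    dist <- gridDistance(drainage)
    relief <- smoothField(nRows, nCols) * reliefFraction * handGainM
    hand <- handGainM * dist + relief
    hand[drainage] <- 0

    # forest may overlap drainage: swamp forest canopy spans watercourses
    forestField <- smoothField(nRows, nCols)
    forest <- forestField <= stats::quantile(forestField, forestFraction)

    methods::new("TerrainModel", handM = hand, forestMask = forest,
                 drainageMask = drainage, pixelSizeM = as.numeric(pixelSizeM))
  })
}
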