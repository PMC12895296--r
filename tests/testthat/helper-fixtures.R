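# Shared fixtures, all generated in code.

smallTerrain <- function(n = 32, seed = 11, ...) {
  generateTerrain(n, n, pixelSizeM = 25, nChannels = 2L, seed = seed, ...)
}

# A flood map built directly from a logical grid (bypassing classification).
mapFromGrid <- function(flooded, year = 2020L, mask = NULL, px = 25) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(flooded), ncol(flooded))
  new("FloodMap", year = as.integer(year), flooded = flooded & mask,
      analysisMask = mask, pixelSizeM = px)
}

# Perfectly separated two-class feature frame: disjoint supports on every
# feature, so any sensible classifier reaches accuracy 1.
separableFeatures <- function(nPerClass = 200, seed = 5) {
  withr::with_seed(seed, {
    swamp <- data.frame(
      hh = runif(nPerClass, -6.5, -5.5), hv = runif(nPerClass, -12.5, -11.5),
      hand = runif(nPerClass, 0, 1))
    dry <- data.frame(
      hh = runif(nPerClass, -9.5, -8.5), hv = runif(nPerClass, -13.5, -12.6),
      hand = runif(nPerClass, 2, 10))
    out <- rbind(swamp, dry)
    out$hvhh <- out$hv - out$hh
    out$label <- factor(rep(c("swamp", "terra_firme"), each = nPerClass),
                        levels = c("swamp", "terra_firme"))
    out
  })
}

# Independent scalar oracle for WTL binning, written from the class
# definitions rather than the package's cut() call.
binWtlOracle <- function(v) {
  labs <- wtlClassLabels()
  vapply(v, function(x) {
    if (x <= -70) labs[1]
    else if (x <= -50) labs[2]
    else if (x <= -30) labs[3]
    else if (x <= -5) labs[4]
    else if (x <= 40) labs[5]
    else labs[6]
  }, character(1))
}

# Brute-force multi-source BFS distance oracle (queen moves), O(n^2 * iter):
# repeated relaxation until fixpoint.
bfsDistanceOracle <- function(sources) {
  nr <- nrow(sources); nc <- ncol(sources)
  d <- matrix(Inf, nr, nc)
  d[sources] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            d[r2, c2] + 1 < d[r, cc]) {
          d[r, cc] <- d[r2, c2] + 1
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}
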