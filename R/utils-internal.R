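# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seeds fanned out from one master seed;
# kept below 2^31 - 1 so they are valid R integers.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# TRUE at [r, c] if any 8-neighbour of [r, c] is TRUE in m.
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rTgt <- seq_len(nr); cTgt <- seq_len(nc)
    rSrc <- rTgt + dr; cSrc <- cTgt + dc
    keepR <- rSrc >= 1L & rSrc <= nr
    keepC <- cSrc >= 1L & cSrc <= nc
    out[rTgt[keepR], cTgt[keepC]] <-
      out[rTgt[keepR], cTgt[keepC]] | m[rSrc[keepR], cSrc[keepC]]
  }
  out
}

# Multi-source breadth-first 8-connected grid distance (in steps) from the
# TRUE pixels of `sources`.
gridDistance <- function(sources) {
  d <- matrix(NA_integer_, nrow(sources), ncol(sources))
  d[sources] <- 0L
  frontier <- sources
  step <- 0L
  while (any(frontier)) {
    step <- step + 1L
    reached <- dilate8(frontier) & is.na(d)
    if (!any(reached)) break
    d[reached] <- step
    frontier <- reached
  }
  d
}

# Smooth random field in [0, 1]: white noise blurred by repeated 3x3 means.
smoothField <- function(nRows, nCols, passes = 4L) {
  f <- matrix(stats::runif(nRows * nCols), nRows, nCols)
  for (i in seq_len(passes)) f <- windowMean(f)
  rng <- range(f)
  if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else f * 0
}

# NA-aware moving-window mean over a square kernel; NA cells are excluded
# from windows and stay NA in the output.
windowMean <- function(m, kernel = 3L) {
  half <- (kernel - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  valid <- !is.na(m)
  vals <- m
  vals[!valid] <- 0
  sums <- matrix(0, nr, nc)
  cnts <- matrix(0, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    rTgt <- seq_len(nr); cTgt <- seq_len(nc)
    rSrc <- rTgt + dr; cSrc <- cTgt + dc
    keepR <- rSrc >= 1L & rSrc <= nr
    keepC <- cSrc >= 1L & cSrc <= nc
    sums[rTgt[keepR], cTgt[keepC]] <-
      sums[rTgt[keepR], cTgt[keepC]] + vals[rSrc[keepR], cSrc[keepC]]
    cnts[rTgt[keepR], cTgt[keepC]] <-
      cnts[rTgt[keepR], cTgt[keepC]] + valid[rSrc[keepR], cSrc[keepC]]
  }
  out <- sums / cnts
  out[cnts == 0 | !valid] <- NA_real_
  out
}

# Moving-window median, same masking semantics as windowMean.
windowMedian <- function(m, kernel = 3L) {
  half <- (kernel - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  offsets <- expand.grid(dr = -half:half, dc = -half:half)
  layers <- matrix(NA_real_, nr * nc, nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    shifted <- matrix(NA_real_, nr, nc)
    rTgt <- seq_len(nr); cTgt <- seq_len(nc)
    rSrc <- rTgt + dr; cSrc <- cTgt + dc
    keepR <- rSrc >= 1L & rSrc <= nr
    keepC <- cSrc >= 1L & cSrc <= nc
    shifted[rTgt[keepR], cTgt[keepC]] <- m[rSrc[keepR], cSrc[keepC]]
    layers[, i] <- as.vector(shifted)
  }
  out <- apply(layers, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nr, nc)
  out[is.na(m)] <- NA_real_
  out
}
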