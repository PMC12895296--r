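#' Delineate the flood-potential domain
#'
#' Forested pixels that could plausibly flood: forest AND Height Above
#' Nearest Drainage at or below the threshold. Pixels with HAND strictly
#' greater than 20 m (default) are removed, so a pixel at exactly 20 m is
#' retained.
#'
#' @param forestMask logical matrix.
#' @param handM numeric HAND matrix (m).
#' @param handThresholdM removal threshold in metres (default 20).
#' @return logical matrix.
#' @examples
#' floodPotentialMask(matrix(TRUE, 1, 3), matrix(c(0, 20, 21), 1), 20)
#' @export
floodPotentialMask <- function(forestMask, handM, handThresholdM = 20) {
  if (!identical(dim(forestMask), dim(handM)))
    .stopf("forestMask and handM must share one shape")
  forestMask & handM <= handThresholdM
}

# Feature frame (HH, HV, HV-HH ratio in dB, HAND) for a set of pixel indices.
.featureFrame <- function(scene, handM, idx) {
  data.frame(
    hh = scene@hhDb[idx],
    hv = scene@hvDb[idx],
    hvhh = scene@hvDb[idx] - scene@hhDb[idx],
    hand = handM[idx]
  )
}

#' Extract classifier features at ground-truth points
#'
#' Per-point HH, HV, the HV/HH ratio (a dB difference) and HAND from one
#' scene. Points on invalid scene pixels are dropped with a warning.
#'
#' @param scene a [BackscatterScene-class].
#' @param handM numeric HAND matrix (m).
#' @param truth a [GroundTruthSet-class].
#' @return data.frame with columns \code{hh}, \code{hv}, \code{hvhh},
#'   \code{hand}, \code{label}.
#' @export
extractFeatures <- function(scene, handM, truth) {
  stopifnot(methods::is(scene, "BackscatterScene"),
            methods::is(truth, "GroundTruthSet"))
  p <- truth@points
  idx <- cbind(p$row, p$col)
  keep <- scene@validMask[idx]
  if (!all(keep)) {
    warning(sprintf("%d ground-truth points fall on invalid pixels and were dropped",
                    sum(!keep)))
    p <- p[keep, , drop = FALSE]
    idx <- idx[keep, , drop = FALSE]
  }
  out <- .featureFrame(scene, handM, idx)
  out$label <- p$label
  out
}

#' Train the flood classifier with a stratified split and holdout report
#'
#' Splits the ground-truth points into training and validation sets by
#' class-stratified random sampling (70/30 by default, per-class counts
#' rounded), fits a random forest (500 trees by default) on the features
#' (HH, HV, HV-HH, HAND), and computes the confusion matrix and accuracies
#' on the held-out points. Deterministic for a fixed seed.
#'
#' @param features data.frame from [extractFeatures()] (columns \code{hh},
#'   \code{hv}, \code{hvhh}, \code{hand}, \code{label}).
#' @param trainFraction fraction of points used for training (default 0.7).
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @return a [FloodClassifier-class].
#' @export
trainFloodClassifier <- function(features, trainFraction = 0.7, nTrees = 500L,
                                 seed = 1L) {
  lab <- features$label
  if (nlevels(droplevels(lab)) < 2L)
    .stopf("training data must contain both classes")
  feat <- features[, c("hh", "hv", "hvhh", "hand")]
  withSeed(seed, {
    trainIdx <- integer(0)
    for (cl in levels(lab)) {
      clIdx <- which(lab == cl)
      nTr <- round(length(clIdx) * trainFraction)
      nTr <- min(max(nTr, 1L), length(clIdx) - 1L)
      trainIdx <- c(trainIdx, sample(clIdx, nTr))
    }
    holdIdx <- setdiff(seq_along(lab), trainIdx)
    if (nlevels(droplevels(lab[trainIdx])) < 2L ||
        nlevels(droplevels(lab[holdIdx])) < 2L)
      .stopf("both classes must be present in the training and holdout splits")
    rf <- randomForest::randomForest(
      x = feat[trainIdx, ], y = lab[trainIdx], ntree = as.integer(nTrees))
    predHold <- .predictFlooded(rf, feat[holdIdx, , drop = FALSE])
    report <- .accuracyReport(predHold, lab[holdIdx])
    methods::new("FloodClassifier", model = rf, report = report,
                 featureNames = names(feat),
                 nTrain = length(trainIdx), nHoldout = length(holdIdx))
  })
}

# Vote-threshold prediction: swamp iff the swamp vote fraction strictly
# exceeds 0.5; ties go to terra_firme (conservative for swamp area).
.predictFlooded <- function(rf, newdata) {
  pr <- stats::predict(rf, newdata = newdata, type = "prob")
  factor(ifelse(pr[, "swamp"] > 0.5, "swamp", "terra_firme"),
         levels = c("swamp", "terra_firme"))
}

.accuracyReport <- function(pred, ref) {
  lev <- c("swamp", "terra_firme")
  cm <- table(factor(pred, lev), factor(ref, lev))
  cm <- matrix(as.integer(cm), 2, 2, dimnames = list(mapped = lev, reference = lev))
  ua <- diag(cm) / rowSums(cm)
  pa <- diag(cm) / colSums(cm)
  names(ua) <- names(pa) <- lev
  methods::new("AccuracyReport", confusion = cm,
               overall = sum(diag(cm)) / sum(cm),
               userAccuracy = ua, producerAccuracy = pa)
}

#' Classify one annual scene into a flood map
#'
#' Applies the trained classifier to every valid pixel inside the
#' flood-potential mask. Invalid pixels are unlabelled: they are excluded
#' from the analysis mask and therefore from all area accounting.
#'
#' @param classifier a [FloodClassifier-class].
#' @param scene a [BackscatterScene-class].
#' @param handM numeric HAND matrix (m).
#' @param potentialMask logical flood-potential mask
#'   (see [floodPotentialMask()]).
#' @param pixelSizeM pixel edge length in metres.
#' @return a [FloodMap-class].
#' @export
classifyYear <- function(classifier, scene, handM, potentialMask,
                         pixelSizeM = 25) {
  if (!methods::is(classifier, "FloodClassifier") ||
      is.null(classifier@model))
    .stopf("classifier has not been trained")
  mask <- potentialMask & scene@validMask
  flooded <- matrix(FALSE, nrow(handM), ncol(handM))
  idx <- which(mask)
  if (length(idx) > 0L) {
    feat <- .featureFrame(scene, handM, idx)
    flooded[idx] <- .predictFlooded(classifier@model, feat) == "swamp"
  }
  methods::new("FloodMap", year = scene@year, flooded = flooded,
               analysisMask = mask, pixelSizeM = as.numeric(pixelSizeM))
}

#' Annual extent series from flood maps
#'
#' Point-estimate areas: flooded pixel count times pixel area, in km^2.
#'
#' @param maps list of [FloodMap-class] objects.
#' @return data.frame with columns \code{year}, \code{areaKm2}.
#' @export
extentSeries <- function(maps) {
  if (length(maps) == 0L) .stopf("maps must be non-empty")
  data.frame(
    year = vapply(maps, function(m) m@year, integer(1)),
    areaKm2 = vapply(maps, function(m) sum(m@flooded) * m@pixelSizeM^2 / 1e6,
                     numeric(1))
  )
}

#' Error-adjusted area estimate with a 95% confidence interval
#'
#' Good-practice stratified area estimation from the confusion matrix:
#' strata are the mapped classes with weights equal to their mapped area
#' proportions; the adjusted swamp-area proportion is
#' \eqn{\hat p_{\cdot k} = \sum_i W_i \, n_{ik} / n_{i\cdot}} and its
#' standard error follows the stratified binomial formula, giving a normal
#' 95% interval. A perfect confusion matrix returns the mapped area with a
#' zero-width interval.
#'
#' @param map a [FloodMap-class].
#' @param report an [AccuracyReport-class] from held-out validation.
#' @return one-row data.frame: \code{year}, \code{areaKm2} (adjusted),
#'   \code{ciLowKm2}, \code{ciHighKm2}, \code{mappedKm2}.
#' @export
errorAdjustedExtent <- function(map, report) {
  stopifnot(methods::is(map, "FloodMap"), methods::is(report, "AccuracyReport"))
  cm <- report@confusion
  nRow <- rowSums(cm)
  if (any(nRow == 0L)) .stopf("every mapped stratum needs validation counts")
  pxArea <- map@pixelSizeM^2 / 1e6
  aMapped <- c(swamp = sum(map@flooded),
               terra_firme = sum(map@analysisMask & !map@flooded)) * pxArea
  total <- sum(aMapped)
  if (total <= 0) .stopf("empty analysis mask")
  W <- aMapped / total
  prop <- cm / nRow  # row-conditional proportions n_ik / n_i.
  pSwamp <- sum(W * prop[, "swamp"])
  varP <- sum(W^2 * prop[, "swamp"] * (1 - prop[, "swamp"]) /
                pmax(nRow - 1L, 1L))
  se <- sqrt(varP) * total
  adj <- pSwamp * total
  data.frame(year = map@year, areaKm2 = adj,
             ciLowKm2 = adj - 1.96 * se, ciHighKm2 = adj + 1.96 * se,
             mappedKm2 = aMapped[["swamp"]])
}

#' Flood loss / gain change map between two periods
#'
#' Per-period flood presence is a strict majority of that period's maps at
#' each pixel (over the years where the pixel was actually classified).
#' Pixels present early only are flood loss; present late only, flood gain;
#' present in both, stable swamp; in neither, terra firme. Only pixels
#' classified in at least one year of both periods are assessed.
#'
#' @param earlyMaps,lateMaps lists of [FloodMap-class] (e.g. the 2007-2010
#'   and 2015-2024 periods).
#' @return list with \code{classes} (character matrix with values
#'   \code{terra_firme}, \code{stable_swamp}, \code{flood_loss},
#'   \code{flood_gain}; NA off-domain) and \code{counts} (named class
#'   pixel counts).
#' @export
changeMap <- function(earlyMaps, lateMaps) {
  if (length(earlyMaps) == 0L || length(lateMaps) == 0L)
    .stopf("both periods need at least one map")
  presence <- function(maps) {
    fl <- Reduce(`+`, lapply(maps, function(m) m@flooded + 0L))
    av <- Reduce(`+`, lapply(maps, function(m) m@analysisMask + 0L))
    list(present = av > 0L & fl > av / 2, assessed = av > 0L)
  }
  e <- presence(earlyMaps)
  l <- presence(lateMaps)
  domain <- e$assessed & l$assessed
  lev <- c("terra_firme", "stable_swamp", "flood_loss", "flood_gain")
  cls <- matrix(NA_character_, nrow(domain), ncol(domain))
  cls[domain & !e$present & !l$present] <- "terra_firme"
  cls[domain & e$present & l$present] <- "stable_swamp"
  cls[domain & e$present & !l$present] <- "flood_loss"
  cls[domain & !e$present & l$present] <- "flood_gain"
  counts <- vapply(lev, function(x) sum(cls == x, na.rm = TRUE), integer(1))
  list(classes = cls, counts = counts)
}
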