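#' Convert digital numbers to gamma naught (dB)
#'
#' Radiometric calibration \eqn{\gamma^0 = 10\log_{10}(DN^2) + CF} with the
#' standard L-band mosaic calibration factor CF = -83 dB by default. Zero
#' digital numbers have no dB representation and are returned as NA (to be
#' held invalid downstream) rather than propagating -Inf.
#'
#' @param dn non-negative numeric matrix of digital numbers.
#' @param calibrationFactorDb calibration constant (dB).
#' @return numeric matrix in dB, NA where \code{dn} is 0 or NA.
#' @examples
#' dnToGamma0(matrix(c(1, 10, 0, 100), 2), -83)
#' @export
dnToGamma0 <- function(dn, calibrationFactorDb = -83) {
  if (any(dn < 0, na.rm = TRUE)) .stopf("digital numbers must be >= 0")
  out <- 10 * log10(dn^2) + calibrationFactorDb
  out[!is.na(dn) & dn == 0] <- NA_real_
  out
}

#' Incidence-angle correction
#'
#' Normalises gamma naught to a reference incidence angle with the cosine
#' -ratio model: \eqn{\gamma^0_{ref} = \gamma^0 - 10 n
#' \log_{10}(\cos\theta / \cos\theta_{ref})}. Pixels already at the
#' reference angle are unchanged; applying the correction and then its
#' inverse (swap the angles) round-trips to the input.
#'
#' @param gamma0Db numeric matrix (dB).
#' @param incidenceDeg numeric matrix or scalar, local incidence angle in
#'   (0, 90) degrees.
#' @param referenceDeg reference angle in (0, 90) degrees (default 38.7).
#' @param exponent cosine-model power \code{n} (default 1).
#' @return corrected numeric matrix (dB).
#' @examples
#' correctIncidenceAngle(matrix(0, 1, 1), 45, 38.7)
#' @export
correctIncidenceAngle <- function(gamma0Db, incidenceDeg, referenceDeg = 38.7,
                                  exponent = 1) {
  if (any(incidenceDeg <= 0 | incidenceDeg >= 90, na.rm = TRUE) ||
      referenceDeg <= 0 || referenceDeg >= 90)
    .stopf("incidence angles must lie strictly between 0 and 90 degrees")
  gamma0Db - 10 * exponent *
    log10(cos(incidenceDeg * pi / 180) / cos(referenceDeg * pi / 180))
}

#' Speckle filter
#'
#' Square-kernel window filter in the dB domain: each valid pixel is
#' replaced by the mean (default) or median of the valid pixels in its
#' \code{kernel} x \code{kernel} window. Invalid (NA) pixels are excluded
#' from every window and remain invalid. \code{kernel = 1} is the identity.
#'
#' @param grid numeric matrix (dB), NA = invalid.
#' @param kernel odd window size (default 3).
#' @param stat \code{"mean"} or \code{"median"}.
#' @return filtered numeric matrix.
#' @examples
#' speckleFilter(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3))[2, 2]
#' @export
speckleFilter <- function(grid, kernel = 3L, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    .stopf("kernel must be an odd integer >= 1 (got %d)", kernel)
  if (kernel == 1L) return(grid)
  if (stat == "mean") windowMean(grid, kernel) else windowMedian(grid, kernel)
}

#' Remove low-quality pixels using the data-quality flags
#'
#' Marks pixels whose quality flag is in \code{badFlagValues} (layover,
#' shadowing, mosaic gaps, ...) as invalid. Values are untouched; only the
#' validity mask changes.
#'
#' @param scene a [BackscatterScene-class].
#' @param badFlagValues integer vector of flag values to reject.
#' @return the scene with an updated valid mask.
#' @export
applyQualityMask <- function(scene, badFlagValues = 1L) {
  stopifnot(methods::is(scene, "BackscatterScene"))
  bad <- matrix(scene@qualityFlags %in% badFlagValues,
                nrow(scene@qualityFlags), ncol(scene@qualityFlags))
  scene@validMask <- scene@validMask & !bad
  methods::validObject(scene)
  scene
}

#' Fill gaps in a scene from a donor year
#'
#' Invalid target pixels take the donor's HH/HV/incidence values wherever
#' the donor is valid (the mosaic gap-filling step, e.g. patching a 2008
#' mosaic from 2007). Filled pixels become valid and are recorded in the
#' scene's filled mask for provenance.
#'
#' @param target,donor [BackscatterScene-class] objects on one grid, from
#'   different years.
#' @return the target scene with gaps filled.
#' @export
fillGaps <- function(target, donor) {
  stopifnot(methods::is(target, "BackscatterScene"),
            methods::is(donor, "BackscatterScene"))
  if (!identical(dim(target@hhDb), dim(donor@hhDb)))
    .stopf("target and donor grids must share one shape")
  if (target@year == donor@year)
    .stopf("donor year must differ from target year")
  fill <- !target@validMask & donor@validMask
  target@hhDb[fill] <- donor@hhDb[fill]
  target@hvDb[fill] <- donor@hvDb[fill]
  target@incidenceDeg[fill] <- donor@incidenceDeg[fill]
  target@validMask <- target@validMask | fill
  target@filledMask <- target@filledMask | fill
  methods::validObject(target)
  target
}

#' Preprocess a scene into analysis-ready form
#'
#' Applies the standard chain on one scene: quality masking, incidence-angle
#' normalisation to the reference angle, and speckle filtering, with
#' DN-to-dB calibration first when the input dialect is digital numbers
#' (scenes generated by this package are already in dB, so calibration is
#' skipped for them).
#'
#' @param scene a [BackscatterScene-class].
#' @param badFlagValues quality-flag values to reject.
#' @param referenceDeg reference incidence angle (degrees).
#' @param kernel speckle-filter window (odd; 1 disables).
#' @param stat speckle statistic, \code{"mean"} or \code{"median"}.
#' @param inputUnits \code{"db"} (default) or \code{"dn"}.
#' @param calibrationFactorDb calibration constant used when
#'   \code{inputUnits = "dn"}.
#' @return an analysis-ready [BackscatterScene-class].
#' @export
preprocessScene <- function(scene, badFlagValues = 1L, referenceDeg = 38.7,
                            kernel = 3L, stat = c("mean", "median"),
                            inputUnits = c("db", "dn"),
                            calibrationFactorDb = -83) {
  stat <- match.arg(stat)
  inputUnits <- match.arg(inputUnits)
  scene <- applyQualityMask(scene, badFlagValues)
  hh <- scene@hhDb; hv <- scene@hvDb
  if (inputUnits == "dn") {
    hh <- dnToGamma0(hh, calibrationFactorDb)
    hv <- dnToGamma0(hv, calibrationFactorDb)
    scene@validMask <- scene@validMask & !is.na(hh) & !is.na(hv)
  }
  hh[!scene@validMask] <- NA_real_
  hv[!scene@validMask] <- NA_real_
  hh <- correctIncidenceAngle(hh, scene@incidenceDeg, referenceDeg)
  hv <- correctIncidenceAngle(hv, scene@incidenceDeg, referenceDeg)
  hh <- speckleFilter(hh, kernel, stat)
  hv <- speckleFilter(hv, kernel, stat)
  scene@hhDb <- hh
  scene@hvDb <- hv
  methods::validObject(scene)
  scene
}
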