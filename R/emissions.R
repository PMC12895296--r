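#' Global-warming-potential weight sets
#'
#' CO2-equivalent weights relative to CO2: 34 (CH4) and 298 (N2O) over a
#' 100-year horizon, 82.5 and 273 over a 20-year horizon.
#'
#' @param horizon \code{"100yr"} (default) or \code{"20yr"}.
#' @return a [GwpWeights-class].
#' @examples
#' gwpWeights("100yr")
#' gwpWeights("20yr")
#' @export
gwpWeights <- function(horizon = c("100yr", "20yr")) {
  horizon <- match.arg(horizon)
  w <- switch(horizon, "100yr" = c(34, 298), "20yr" = c(82.5, 273))
  methods::new("GwpWeights", horizon = horizon, wCh4 = w[1], wN2o = w[2])
}

#' CO2-equivalent aggregation
#'
#' Weighted sum of the three gas fluxes,
#' \eqn{CO_2eq = CO_2 + w_{CH_4} CH_4 + w_{N_2O} N_2O}, with the weights of
#' the chosen horizon (100-yr: 34 and 298; 20-yr: 82.5 and 273). Signed
#' fluxes are allowed: sinks are negative. Vectorised over the gas
#' arguments.
#'
#' @param co2,ch4,n2o fluxes in common mass units (e.g. t yr^-1).
#' @param weights a [GwpWeights-class] (default the 100-year set).
#' @return CO2-equivalent flux, same units as the inputs.
#' @examples
#' co2Equivalent(0, 1, 0)                      # 34
#' co2Equivalent(0, 0, 1)                      # 298
#' co2Equivalent(0, 1, 0, gwpWeights("20yr"))  # 82.5
#' @export
co2Equivalent <- function(co2, ch4, n2o, weights = gwpWeights("100yr")) {
  stopifnot(methods::is(weights, "GwpWeights"))
  co2 + weights@wCh4 * ch4 + weights@wN2o * n2o
}

# normalise a class-areas input (data.frame from wtlClassAreas, or a named
# vector) to a named numeric vector over the six canonical classes.
.classAreaVector <- function(areas) {
  if (is.data.frame(areas)) {
    v <- stats::setNames(areas$areaKm2, areas$class)
  } else {
    v <- areas
  }
  if (!setequal(names(v), wtlClassLabels()))
    .stopf("class areas must cover exactly the six canonical WTL classes")
  v[wtlClassLabels()]
}

#' Annual emissions from WTL class areas and a flux table
#'
#' Per gas, the annual total is the sum over the six WTL classes of class
#' area times that class's flux density; 95% bounds apply the same sum with
#' the lower/upper flux densities (areas enter as point estimates).
#' CO2-equivalents at both horizons are computed from the per-gas totals
#' (bound-wise for the CIs — valid because the weights are positive).
#'
#' @param areas one year's class areas: the data.frame from
#'   [wtlClassAreas()] or a named vector (km^2) over the six classes.
#' @param table a [FluxTable-class] (t km^-2 yr^-1).
#' @param year integer year attached to the output (taken from \code{areas}
#'   when it is a data.frame).
#' @return data.frame with one row per quantity (\code{CO2}, \code{CH4},
#'   \code{N2O}, \code{CO2eq_100yr}, \code{CO2eq_20yr}) and columns
#'   \code{year}, \code{quantity}, \code{total}, \code{ciLow},
#'   \code{ciHigh}, in t yr^-1.
#' @examples
#' a <- setNames(c(0, 0, 0, 0, 10, 0), wtlClassLabels())
#' annualEmissions(a, defaultFluxTable(), year = 2020)
#' @export
annualEmissions <- function(areas, table, year = NA_integer_) {
  stopifnot(methods::is(table, "FluxTable"))
  if (is.data.frame(areas) && "year" %in% names(areas) && is.na(year))
    year <- areas$year[1L]
  a <- .classAreaVector(areas)
  tb <- table@table
  gasTotal <- function(gas, col) {
    rows <- tb[tb$gas == gas, ]
    dens <- stats::setNames(rows[[col]], rows$class)[wtlClassLabels()]
    sum(a * dens)
  }
  gases <- c("CO2", "CH4", "N2O")
  tot <- vapply(gases, gasTotal, numeric(1), col = "mean")
  lo <- vapply(gases, gasTotal, numeric(1), col = "ciLow")
  hi <- vapply(gases, gasTotal, numeric(1), col = "ciHigh")
  w100 <- gwpWeights("100yr"); w20 <- gwpWeights("20yr")
  eq <- function(v, w) co2Equivalent(v[["CO2"]], v[["CH4"]], v[["N2O"]], w)
  data.frame(
    year = as.integer(year),
    quantity = c(gases, "CO2eq_100yr", "CO2eq_20yr"),
    total = c(tot, eq(tot, w100), eq(tot, w20)),
    ciLow = c(lo, eq(lo, w100), eq(lo, w20)),
    ciHigh = c(hi, eq(hi, w100), eq(hi, w20)),
    row.names = NULL
  )
}

#' Emissions series over years
#'
#' Applies [annualEmissions()] to each year's class areas.
#'
#' @param areasByYear list of per-year class-area data.frames (from
#'   [wtlClassAreas()]), or one long data.frame with a \code{year} column.
#' @param table a [FluxTable-class].
#' @return long data.frame, one row per year and quantity.
#' @export
emissionsSeries <- function(areasByYear, table) {
  if (is.data.frame(areasByYear))
    areasByYear <- split(areasByYear, areasByYear$year)
  years <- vapply(areasByYear, function(a) as.integer(a$year[1L]), integer(1))
  if (anyDuplicated(years)) .stopf("years must be distinct")
  out <- do.call(rbind, lapply(areasByYear, annualEmissions, table = table))
  rownames(out) <- NULL
  out
}
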