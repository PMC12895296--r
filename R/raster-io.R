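#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange for single-band grids. The format stores one
#' band as a header (\code{ncols}, \code{nrows}, \code{xllcorner},
#' \code{yllcorner}, \code{cellsize}, \code{NODATA_value}) followed by rows
#' of whitespace-separated values, top row first. NA values are written as
#' the nodata value and restored to NA on read; logical grids round-trip as
#' 0/1.
#'
#' @param m numeric or logical matrix.
#' @param path file path (conventionally \code{.asc}).
#' @param cellSize pixel edge length in the grid's units (metres here).
#' @param nodata numeric nodata sentinel written for NA cells.
#' @param xll,yll lower-left corner coordinates (arbitrary local origin).
#' @return \code{writeAsciiGrid} returns \code{path} invisibly;
#'   \code{readAsciiGrid} returns a list with elements \code{grid} (numeric
#'   matrix, NA where nodata) and \code{cellSize}.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(matrix(1:6, 2), f, cellSize = 25)
#' readAsciiGrid(f)$grid
#' @export
writeAsciiGrid <- function(m, path, cellSize = 1, nodata = -9999,
                           xll = 0, yll = 0) {
  if (is.logical(m)) m <- m + 0
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", xll),
    sprintf("yllcorner %.6f", yll),
    sprintf("cellsize %.6f", cellSize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(format(m, trim = TRUE, digits = 10, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    .stopf("ASCII grid body has %d values, expected %d", length(body), nr * nc)
  g <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == nodata] <- NA_real_
  list(grid = g, cellSize = vals[["cellsize"]])
}
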