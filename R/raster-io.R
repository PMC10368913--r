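#' Read an ESRI ASCII grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by row-major cell values (row 1 =
#' northernmost). Only single-band square-cell grids exist in this
#' format. Categorical grids must hold exact integers.
#'
#' @param path file path.
#' @param kind `"categorical"` or `"continuous"`.
#' @param legend legend for categorical rasters (default [lulcLegend()]).
#' @param units unit label attached to continuous rasters.
#' @return a [CategoricalRaster-class] or [ContinuousRaster-class].
#' @seealso [writeAsciiGrid()]
#' @export
readAsciiGrid <- function(path, kind = c("categorical", "continuous"),
                          legend = lulcLegend(), units = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cells, found %d in %s", nr * nc, length(vals),
                 path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid <- gridSpec2(nr, nc, cellsize = hdr$cellsize,
                    origin = c(hdr$xllcorner,
                               hdr$yllcorner + nr * hdr$cellsize),
                    nodata = nodata)
  if (kind == "categorical") {
    ok <- m == nodata | m == round(m)
    if (!all(ok)) stop("non-integer values in categorical grid ", path)
    categoricalRaster(m, grid = grid, legend = legend)
  } else {
    continuousRaster(m, grid = grid, units = units)
  }
}

#' Write an ESRI ASCII grid
#'
#' Categorical rasters round-trip bit-faithfully; continuous values are
#' written with 12 significant digits (far inside a 1e-6 relative
#' round-trip tolerance). The format requires square cells.
#'
#' @param x a [CategoricalRaster-class], [ContinuousRaster-class] or
#'   [FuzzyLayer-class] (written as its membership surface).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeAsciiGrid <- function(x, path) {
  grid <- gridSpec(x)
  if (abs(grid@cellsizeX - grid@cellsizeY) > 1e-12)
    stop("ESRI ASCII grids require square cells")
  v <- if (is(x, "CategoricalRaster")) x@values
       else if (is(x, "FuzzyLayer")) x@memberships
       else x@values
  hdr <- c(
    sprintf("ncols %d", grid@ncols),
    sprintf("nrows %d", grid@nrows),
    sprintf("xllcorner %.10g", grid@originX),
    sprintf("yllcorner %.10g", grid@originY - grid@nrows * grid@cellsizeY),
    sprintf("cellsize %.10g", grid@cellsizeX),
    sprintf("NODATA_value %.10g", grid@nodata)
  )
  body <- apply(v, 1L, function(row) {
    if (is.integer(row)) paste(row, collapse = " ")
    else paste(sprintf("%.12g", row), collapse = " ")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
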