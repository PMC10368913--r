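#' Construct a GridSpec
#'
#' @param nrows,ncols grid dimensions.
#' @param cellsize cell edge length in metres; a single value gives square
#'   cells, a length-2 vector gives `c(x, y)`.
#' @param origin map coordinate `c(x, y)` of the top-left corner.
#' @param crs optional CRS identifier (free text, never compared).
#' @param nodata nodata sentinel value.
#' @return a [GridSpec-class].
#' @examples
#' gridSpec2(10, 10, cellsize = 10)
#' @export
gridSpec2 <- function(nrows, ncols, cellsize = 10, origin = c(0, 0),
                      crs = NA_character_, nodata = -9999) {
  cellsize <- rep_len(as.numeric(cellsize), 2L)
  new("GridSpec",
      nrows = as.integer(nrows), ncols = as.integer(ncols),
      cellsizeX = cellsize[1L], cellsizeY = cellsize[2L],
      originX = as.numeric(origin[1L]), originY = as.numeric(origin[2L]),
      crs = as.character(crs), nodata = as.numeric(nodata))
}

#' Default land-cover legend
#'
#' Class codes fixed across the package for deterministic joins between
#' rasters, coefficient tables and reports: 1 agriculture, 2 forest,
#' 3 settlement, 4 water.
#' @return named character vector (names are codes).
#' @export
lulcLegend <- function() {
  c(`1` = "agriculture", `2` = "forest", `3` = "settlement", `4` = "water")
}

#' Construct a categorical raster
#'
#' @param values integer matrix of class codes (NA allowed; converted to
#'   the nodata sentinel).
#' @param grid a [GridSpec-class]; defaults to a 10 m grid matching
#'   `dim(values)`.
#' @param legend named character vector mapping codes to class names.
#' @return a [CategoricalRaster-class].
#' @export
categoricalRaster <- function(values, grid = NULL, legend = lulcLegend()) {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- gridSpec2(nrow(values), ncol(values))
  storage.mode(values) <- "integer"
  values[is.na(values)] <- as.integer(grid@nodata)
  new("CategoricalRaster", grid = grid, values = values, legend = legend)
}

#' Construct a continuous raster
#'
#' @param values numeric matrix (NA converted to the nodata sentinel).
#' @param grid a [GridSpec-class]; defaulted from `dim(values)`.
#' @param units unit label.
#' @return a [ContinuousRaster-class].
#' @export
continuousRaster <- function(values, grid = NULL, units = "") {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- gridSpec2(nrow(values), ncol(values))
  storage.mode(values) <- "double"
  values[is.na(values)] <- grid@nodata
  new("ContinuousRaster", grid = grid, values = values, units = units)
}

#' @describeIn gridSpec grid of a categorical raster
#' @export
setMethod("gridSpec", "CategoricalRaster", function(x) x@grid)
#' @describeIn gridSpec grid of a continuous raster
#' @export
setMethod("gridSpec", "ContinuousRaster", function(x) x@grid)
#' @describeIn gridSpec grid of a fuzzy layer
#' @export
setMethod("gridSpec", "FuzzyLayer", function(x) x@grid)

#' Accessors for raster objects
#'
#' `gridSpec()` returns the [GridSpec-class]; `rasterValues()` the value
#' matrix with nodata cells as `NA`; `classLegend()` the code-to-name
#' legend of a categorical raster.
#'
#' @param x a raster object.
#' @name gridSpec
NULL

#' @rdname rasterValues
#' @param x a raster object.
#' @export
setMethod("rasterValues", "CategoricalRaster", function(x) {
  v <- x@values
  v[v == as.integer(x@grid@nodata)] <- NA_integer_
  v
})
#' @rdname rasterValues
#' @export
setMethod("rasterValues", "ContinuousRaster", function(x) {
  v <- x@values
  v[v == x@grid@nodata] <- NA_real_
  v
})
#' @rdname rasterValues
#' @export
setMethod("rasterValues", "FuzzyLayer", function(x) {
  v <- x@memberships
  v[v == x@grid@nodata] <- NA_real_
  v
})

#' Value matrix of a raster with nodata as NA
#' @name rasterValues
NULL

#' @rdname classLegend
#' @param x a [CategoricalRaster-class].
#' @export
setMethod("classLegend", "CategoricalRaster", function(x) x@legend)

#' Legend of a categorical raster
#' @name classLegend
NULL

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, %g x %g m, origin (%g, %g), nodata %g\n",
              object@nrows, object@ncols, object@cellsizeX, object@cellsizeY,
              object@originX, object@originY, object@nodata))
})

setMethod("show", "CategoricalRaster", function(object) {
  cat(sprintf("CategoricalRaster: %d x %d cells (%g m), %d classes\n",
              object@grid@nrows, object@grid@ncols, object@grid@cellsizeX,
              length(object@legend)))
  tab <- table(factor(rasterValues(object), levels = names(object@legend),
                      labels = object@legend))
  print(tab)
})

setMethod("show", "ContinuousRaster", function(object) {
  v <- rasterValues(object)
  cat(sprintf("ContinuousRaster: %d x %d cells (%g m)%s, range [%g, %g]\n",
              object@grid@nrows, object@grid@ncols, object@grid@cellsizeX,
              if (nzchar(object@units)) paste0(" [", object@units, "]") else "",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "FuzzyLayer", function(object) {
  v <- rasterValues(object)
  cat(sprintf("FuzzyLayer '%s': %d x %d cells, mean membership %.3f\n",
              object@source, object@grid@nrows, object@grid@ncols,
              mean(v, na.rm = TRUE)))
})

.gridsAligned <- function(a, b) {
  fields <- c("nrows", "ncols", "cellsizeX", "cellsizeY", "originX", "originY",
              "nodata")
  for (f in fields) if (!isTRUE(all.equal(slot(a, f), slot(b, f)))) return(f)
  TRUE
}

#' Assert that raster layers share one grid
#'
#' Overlay operations are cell-wise and never resample, so all layers
#' must sit on the identical grid (dimensions, cell size, origin and
#' nodata sentinel; the CRS text is not compared). Errors name the first
#' offending layer and field.
#'
#' @param ... two or more raster objects (any mix of classes), or a
#'   single list of them. Names, if given, are used in error messages.
#' @return invisibly `TRUE` if all grids are aligned.
#' @export
assertAligned <- function(...) {
  rasters <- list(...)
  if (length(rasters) == 1L && is.list(rasters[[1L]]) &&
      !isVirtualClass(class(rasters[[1L]])))
    rasters <- rasters[[1L]]
  if (length(rasters) < 2L)
    stop("assertAligned() needs at least two rasters")
  nms <- names(rasters)
  if (is.null(nms)) nms <- paste0("raster ", seq_along(rasters))
  ref <- gridSpec(rasters[[1L]])
  for (i in seq_along(rasters)[-1L]) {
    res <- .gridsAligned(ref, gridSpec(rasters[[i]]))
    if (!isTRUE(res))
      stop(sprintf("'%s' is misaligned with '%s': field '%s' differs",
                   nms[i], nms[1L], res))
  }
  invisible(TRUE)
}

.cellAreaHa <- function(grid) grid@cellsizeX * grid@cellsizeY / 1e4

#' Per-class area accounting
#'
#' Tabulates the valid (non-nodata) cells of a LULC raster and converts
#' counts to hectares: \eqn{A_k = n_k \cdot \Delta x \cdot \Delta y /
#' 10^4}. Percentages are relative to the valid-cell total. This is the
#' \eqn{A_k} feeding the benefit-transfer valuation.
#'
#' @param x a [CategoricalRaster-class].
#' @param ... unused.
#' @return a `data.frame` with columns `code`, `class`, `cells`,
#'   `area_ha`, `percent`, plus attributes `total_area_ha` and
#'   `cell_area_ha`.
#' @examples
#' r <- categoricalRaster(matrix(2L, 10, 10))   # 100 forest cells at 10 m
#' areaByClass(r)                               # 1 ha of forest
#' @export
setMethod("areaByClass", "CategoricalRaster", function(x, ...) {
  v <- rasterValues(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("raster has no valid cells (all nodata)")
  codes <- as.integer(names(x@legend))
  n <- vapply(codes, function(k) sum(v == k), integer(1))
  area <- n * .cellAreaHa(x@grid)
  out <- data.frame(code = codes, class = unname(x@legend), cells = n,
                    area_ha = area, percent = 100 * n / length(v))
  attr(out, "total_area_ha") <- length(v) * .cellAreaHa(x@grid)
  attr(out, "cell_area_ha") <- .cellAreaHa(x@grid)
  out
})

#' Area table from typed-in per-class areas
#'
#' Builds the same table [areaByClass()] produces, from areas in
#' hectares, so printed area tables can drive the valuation directly
#' without rasterising them.
#'
#' @param ... named areas in hectares, or a single named numeric vector.
#' @return a `data.frame` in the [areaByClass()] layout (cell counts NA).
#' @examples
#' areaTable(agriculture = 11711.33, forest = 24982.31,
#'           settlement = 15614, water = 4999.61)
#' @export
areaTable <- function(...) {
  a <- c(...)
  if (is.null(names(a)) || any(!nzchar(names(a))))
    stop("areas must be named by class")
  if (any(a < 0)) stop("areas must be non-negative")
  out <- data.frame(code = NA_integer_, class = names(a), cells = NA_integer_,
                    area_ha = as.numeric(a),
                    percent = 100 * as.numeric(a) / sum(a))
  leg <- lulcLegend()
  m <- match(out$class, leg)
  out$code <- as.integer(names(leg)[m])
  attr(out, "total_area_ha") <- sum(a)
  out
}
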