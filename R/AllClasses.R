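#' @import methods
NULL

#' Grid geometry of a raster layer
#'
#' A `GridSpec` records the geometry shared by all layers in an overlay
#' stack: grid dimensions, cell size in metres, the map coordinate of the
#' top-left corner (row 1 is the northernmost row), an optional CRS
#' identifier and the nodata sentinel. Two grids are *aligned* when every
#' field except the CRS text matches exactly; all cell-wise operations in
#' the package require aligned inputs and refuse to resample.
#'
#' @slot nrows,ncols grid dimensions (positive integers).
#' @slot cellsizeX,cellsizeY cell edge lengths in metres (positive).
#' @slot originX,originY map coordinates of the top-left corner.
#' @slot crs free-text CRS identifier, `NA` if unknown; never compared.
#' @slot nodata numeric sentinel marking missing cells.
#' @export
setClass("GridSpec",
  representation(
    nrows = "integer", ncols = "integer",
    cellsizeX = "numeric", cellsizeY = "numeric",
    originX = "numeric", originY = "numeric",
    crs = "character", nodata = "numeric"
  ),
  prototype(crs = NA_character_, nodata = -9999)
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrows) != 1L || is.na(object@nrows) || object@nrows < 1L)
    msg <- c(msg, "nrows must be a single positive integer")
  if (length(object@ncols) != 1L || is.na(object@ncols) || object@ncols < 1L)
    msg <- c(msg, "ncols must be a single positive integer")
  if (!isTRUE(object@cellsizeX > 0) || !isTRUE(object@cellsizeY > 0))
    msg <- c(msg, "cell sizes must be positive")
  if (length(object@nodata) != 1L || is.na(object@nodata))
    msg <- c(msg, "nodata must be a single non-NA numeric sentinel")
  if (length(msg)) msg else TRUE
})

#' Integer-coded categorical raster with a class legend
#'
#' Holds a land-use/land-cover (LULC) map: an integer matrix of class
#' codes plus a legend mapping each code to a class name. Cells equal to
#' the grid's nodata sentinel are missing. The default legend used
#' throughout the package is `1` agriculture, `2` forest, `3` settlement,
#' `4` water.
#'
#' @slot grid a [GridSpec-class].
#' @slot values integer matrix, `nrows x ncols`.
#' @slot legend named character vector; names are the integer codes.
#' @export
setClass("CategoricalRaster",
  representation(grid = "GridSpec", values = "matrix", legend = "character")
)

setValidity("CategoricalRaster", function(object) {
  msg <- character()
  v <- object@values
  if (!is.integer(v))
    msg <- c(msg, "values must be an integer matrix")
  if (!identical(dim(v), c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, "values dimensions must match the GridSpec")
  codes <- suppressWarnings(as.integer(names(object@legend)))
  if (length(object@legend) == 0L || anyNA(codes) || any(codes < 0L))
    msg <- c(msg, "legend codes must be non-negative integers")
  valid <- v[!is.na(v) & v != object@grid@nodata]
  if (length(valid) && !all(valid %in% codes))
    msg <- c(msg, "every non-nodata value must appear in the legend")
  if (length(msg)) msg else TRUE
})

#' Continuous-valued raster layer
#'
#' A real-valued surface (land surface temperature in degrees C,
#' population per cell, carbon flux per hectare, an ecosystem-function
#' value surface, ...). Non-nodata cells must be finite.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix.
#' @slot units free-text unit label.
#' @export
setClass("ContinuousRaster",
  representation(grid = "GridSpec", values = "matrix", units = "character"),
  prototype(units = "")
)

setValidity("ContinuousRaster", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (!identical(dim(v), c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, "values dimensions must match the GridSpec")
  valid <- v[!is.na(v) & v != object@grid@nodata]
  if (length(valid) && !all(is.finite(valid)))
    msg <- c(msg, "non-nodata values must be finite")
  if (length(msg)) msg else TRUE
})

#' Fuzzy membership layer
#'
#' A raster of fuzzy membership values in [0, 1] obtained by applying a
#' membership function to a raw parameter layer, or by combining other
#' fuzzy layers with an overlay operator. By the package's direction-free
#' convention a membership near 1 always means a *deteriorating*
#' ecological-quality signal.
#'
#' @slot grid a [GridSpec-class].
#' @slot memberships numeric matrix in [0, 1] (nodata sentinel allowed).
#' @slot source name of the raw parameter or operator that produced it.
#' @slot direction note on how the raw variable maps to degradation.
#' @export
setClass("FuzzyLayer",
  representation(grid = "GridSpec", memberships = "matrix",
                 source = "character", direction = "character"),
  prototype(source = "", direction = "")
)

setValidity("FuzzyLayer", function(object) {
  msg <- character()
  m <- object@memberships
  if (!identical(dim(m), c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, "membership dimensions must match the GridSpec")
  valid <- m[!is.na(m) & m != object@grid@nodata]
  if (length(valid) && (any(valid < 0) || any(valid > 1)))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Markovian class-transition matrix between two dates
#'
#' Raw pixel counts and row-stochastic transition probabilities
#' \eqn{p_{ij}} between the classes of a "before" raster (rows) and an
#' "after" raster (columns), over the jointly valid cells. Rows with a
#' zero before-date count carry `NA` probabilities rather than fake
#' zeros.
#'
#' @slot counts class x class integer matrix of pixel counts.
#' @slot probabilities row-stochastic numeric matrix (`NA` rows allowed).
#' @slot labels class names, in code order.
#' @slot cellAreaHa area of one cell in hectares.
#' @export
setClass("LulcTransitionMatrix",
  representation(counts = "matrix", probabilities = "matrix",
                 labels = "character", cellAreaHa = "numeric")
)

setValidity("LulcTransitionMatrix", function(object) {
  msg <- character()
  cnt <- object@counts
  p <- object@probabilities
  if (nrow(cnt) != ncol(cnt)) msg <- c(msg, "counts must be square")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(dim(cnt), dim(p)))
    msg <- c(msg, "counts and probabilities must have identical dimensions")
  if (length(object@labels) != nrow(cnt))
    msg <- c(msg, "labels must match matrix dimension")
  rs <- rowSums(p)
  live <- rowSums(cnt) > 0
  if (any(live) && any(abs(rs[live] - 1) > 1e-9))
    msg <- c(msg, "rows with counts must sum to 1 within 1e-9")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
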