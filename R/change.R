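#' Markovian transition matrix between two dates
#'
#' Cross-tabulates the jointly valid cells of two aligned categorical
#' rasters sharing one legend. Row i, column j counts the cells that
#' were class i at the first date and class j at the second;
#' probabilities are row-normalised counts \eqn{p_{ij} =
#' n_{ij}/n_{i\cdot}}. Cells nodata at either date are excluded and
#' reported; rows absent at the first date get `NA` probabilities.
#'
#' @param t0,t1 before/after [CategoricalRaster-class] objects.
#' @return a [LulcTransitionMatrix-class].
#' @examples
#' a <- categoricalRaster(matrix(c(1L, 1L, 2L, 2L), 2))
#' b <- categoricalRaster(matrix(c(1L, 2L, 2L, 2L), 2))
#' transitionProbabilities(transitionMatrix(a, b))
#' @export
transitionMatrix <- function(t0, t1) {
  assertAligned(before = t0, after = t1)
  if (!identical(classLegend(t0), classLegend(t1)))
    stop("rasters must share one legend")
  leg <- classLegend(t0)
  v0 <- rasterValues(t0); v1 <- rasterValues(t1)
  joint <- !is.na(v0) & !is.na(v1)
  dropped <- sum(!joint) - sum(is.na(v0) & is.na(v1))
  if (dropped > 0)
    message(dropped, " cell(s) nodata at exactly one date excluded")
  if (!any(joint)) stop("no jointly valid cells")
  codes <- names(leg)
  tab <- table(factor(v0[joint], levels = codes),
               factor(v1[joint], levels = codes))
  cnt <- matrix(as.integer(tab), length(codes), length(codes),
                dimnames = list(unname(leg), unname(leg)))
  rs <- rowSums(cnt)
  p <- cnt / ifelse(rs > 0, rs, NA_real_)
  new("LulcTransitionMatrix", counts = cnt, probabilities = p,
      labels = unname(leg), cellAreaHa = .cellAreaHa(gridSpec(t0)))
}

#' @rdname transitionCounts
#' @export
setMethod("transitionCounts", "LulcTransitionMatrix", function(x) x@counts)

#' Raw pixel counts of a transition matrix
#' @param x a [LulcTransitionMatrix-class].
#' @name transitionCounts
NULL

#' @rdname transitionProbabilities
#' @export
setMethod("transitionProbabilities", "LulcTransitionMatrix",
          function(x) x@probabilities)

#' Row-stochastic probabilities of a transition matrix
#' @param x a [LulcTransitionMatrix-class].
#' @name transitionProbabilities
NULL

setMethod("show", "LulcTransitionMatrix", function(object) {
  cat(sprintf("LulcTransitionMatrix: %d classes, %d cells (%g ha/cell)\n",
              length(object@labels), sum(object@counts),
              object@cellAreaHa))
  print(round(object@probabilities, 4))
})

#' Per-class net area change between two dates
#'
#' \eqn{\Delta_k = A_k(t_1) - A_k(t_0)} in hectares, and in percentage
#' points of the total area. Accepts rasters or area tables (the
#' [areaByClass()] / [areaTable()] layout), so printed area tables can
#' be analysed directly.
#'
#' @param t0,t1 [CategoricalRaster-class] objects or area data.frames.
#' @return data.frame with columns `class`, `area0_ha`, `area1_ha`,
#'   `change_ha`, `change_pp`.
#' @export
netChange <- function(t0, t1) {
  toAreas <- function(x) if (is.data.frame(x)) x else areaByClass(x)
  a0 <- toAreas(t0); a1 <- toAreas(t1)
  if (!identical(a0$class, a1$class))
    stop("area tables must share one class set")
  total <- sum(a0$area_ha)
  data.frame(class = a0$class, area0_ha = a0$area_ha, area1_ha = a1$area_ha,
             change_ha = a1$area_ha - a0$area_ha,
             change_pp = 100 * (a1$area_ha - a0$area_ha) / total)
}

#' Alluvial flow table between two dates
#'
#' Decomposes the transition counts into one row per ordered class pair
#' with a nonzero flow, in hectares and km². Out-flows of a class sum
#' to its first-date area and in-flows to its second-date area over the
#' jointly valid cells — the marginal-conserving decomposition an
#' alluvial plot displays.
#'
#' @param t0,t1 before/after [CategoricalRaster-class] objects.
#' @return data.frame with columns `from`, `to`, `area_ha`, `area_km2`.
#' @export
flowTable <- function(t0, t1) {
  tm <- transitionMatrix(t0, t1)
  cnt <- transitionCounts(tm)
  idx <- which(cnt > 0, arr.ind = TRUE)
  ha <- cnt[idx] * tm@cellAreaHa
  out <- data.frame(from = tm@labels[idx[, 1L]], to = tm@labels[idx[, 2L]],
                    area_ha = ha, area_km2 = ha / 100)
  out[order(match(out$from, tm@labels), match(out$to, tm@labels)), ,
      drop = FALSE]
}

#' Export a transition matrix for plotting
#'
#' Writes the probabilities as delimited text with class labels, rows =
#' earlier date, columns = later date (heat-map convention).
#'
#' @param tm a [LulcTransitionMatrix-class].
#' @param path output path.
#' @param what `"probabilities"` or `"counts"`.
#' @return invisibly, `path`.
#' @export
writeTransitionMatrix <- function(tm, path,
                                  what = c("probabilities", "counts")) {
  what <- match.arg(what)
  m <- if (what == "probabilities") tm@probabilities else tm@counts
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
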