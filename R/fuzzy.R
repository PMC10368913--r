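.fuzzyLayer <- function(vals, grid, source = "", direction = "") {
  vals[is.na(vals)] <- grid@nodata
  new("FuzzyLayer", grid = grid, memberships = vals, source = source,
      direction = direction)
}

#' Fuzzify a continuous raster
#'
#' Maps a raw parameter layer onto fuzzy memberships in [0, 1]. The
#' sigmoid shapes are
#' \deqn{\mathrm{large}: \mu(x) = \frac{1}{1 + (x/m)^{-s}}, \qquad
#'       \mathrm{small}: \mu(x) = \frac{1}{1 + (x/m)^{s}}}
#' with midpoint `m` (where membership is exactly 0.5) and spread `s`;
#' they require strictly positive inputs. The linear variants ramp
#' 0 to 1 (`linear_large`) or 1 to 0 (`linear_small`) between `bounds`,
#' clamped outside. Nodata propagates.
#'
#' In the ecological-quality model the "large" shape is used where a
#' high raw value degrades EQ (population, LST, carbon flux) and the
#' "small" shape where a *low* value signals degradation (the four
#' ecosystem-function surfaces), making every layer direction-free:
#' membership near 1 always means a deteriorating signal.
#'
#' @param layer a [ContinuousRaster-class].
#' @param shape `"small"`, `"large"`, `"linear_small"`, `"linear_large"`.
#' @param midpoint sigmoid midpoint in input units; defaults to the
#'   midrange of the layer's valid values (echoed via message).
#' @param spread sigmoid spread (default 5).
#' @param bounds length-2 `c(min, max)` for the linear shapes; defaults
#'   to the valid value range.
#' @return a [FuzzyLayer-class].
#' @examples
#' r <- continuousRaster(matrix(c(10, 30, 60), 1))
#' rasterValues(fuzzify(r, "large", midpoint = 30, spread = 5))
#' @export
fuzzify <- function(layer, shape = c("small", "large", "linear_small",
                                     "linear_large"),
                    midpoint = NULL, spread = 5, bounds = NULL) {
  shape <- match.arg(shape)
  x <- rasterValues(layer)
  valid <- x[!is.na(x)]
  mu <- matrix(NA_real_, nrow(x), ncol(x))
  if (shape %in% c("small", "large")) {
    if (any(valid <= 0))
      stop("sigmoid membership needs strictly positive inputs; ",
           "shift the layer or use a linear shape")
    if (is.null(midpoint)) {
      midpoint <- (min(valid) + max(valid)) / 2
      message(sprintf("fuzzify: defaulting midpoint to midrange %.4g",
                      midpoint))
    }
    if (midpoint <= 0 || spread <= 0)
      stop("midpoint and spread must be positive")
    s <- if (shape == "large") -spread else spread
    mu[!is.na(x)] <- 1 / (1 + (valid / midpoint)^s)
  } else {
    if (is.null(bounds)) {
      bounds <- range(valid)
      message(sprintf("fuzzify: defaulting bounds to value range [%.4g, %.4g]",
                      bounds[1], bounds[2]))
    }
    if (bounds[1] >= bounds[2]) stop("bounds must satisfy min < max")
    ramp <- pmin(1, pmax(0, (valid - bounds[1]) / (bounds[2] - bounds[1])))
    mu[!is.na(x)] <- if (shape == "linear_large") ramp else 1 - ramp
  }
  .fuzzyLayer(mu, gridSpec(layer), source = shape,
              direction = if (grepl("large", shape))
                "high raw value -> high membership"
              else "low raw value -> high membership")
}

# stack aligned fuzzy layers into an n_valid x K matrix + NA mask
.fuzzyStack <- function(layers) {
  if (length(layers) < 2L) stop("need at least two fuzzy layers")
  assertAligned(layers)
  vals <- lapply(layers, rasterValues)
  arr <- simplify2array(vals)            # nrows x ncols x K
  arr
}

.combineFuzzy <- function(layers, f, source) {
  arr <- .fuzzyStack(layers)
  out <- apply(arr, c(1L, 2L), function(m) {
    if (anyNA(m)) NA_real_ else f(m)
  })
  .fuzzyLayer(out, gridSpec(layers[[1L]]), source = source,
              direction = "combined")
}

#' Fuzzy overlay operators
#'
#' Cell-wise combination of aligned membership layers. `fuzzyAnd()` is
#' the minimum (pessimistic overlay), `fuzzyOr()` the maximum
#' (optimistic overlay), and `fuzzyGamma()` interpolates between the
#' fuzzy algebraic product and algebraic sum:
#' \deqn{\mu = \Big(1 - \prod_i (1-\mu_i)\Big)^{\gamma}
#'       \Big(\prod_i \mu_i\Big)^{1-\gamma}}
#' so that `gamma = 0` gives the product and `gamma = 1` the sum.
#' Nodata in any input propagates.
#'
#' @param ... two or more [FuzzyLayer-class] objects, or one list of
#'   them.
#' @return a [FuzzyLayer-class].
#' @examples
#' a <- continuousRaster(matrix(0.5, 2, 2))
#' la <- fuzzify(a, "linear_large", bounds = c(0, 1))
#' rasterValues(fuzzyGamma(la, la, gamma = 0.9))  # 0.672 everywhere
#' @export
fuzzyAnd <- function(...) {
  .combineFuzzy(.layerList(...), min, "AND")
}

#' @rdname fuzzyAnd
#' @export
fuzzyOr <- function(...) {
  .combineFuzzy(.layerList(...), max, "OR")
}

#' @rdname fuzzyAnd
#' @param gamma exponent in [0, 1]; 0.9 is the operating point of the
#'   ecological-quality model.
#' @export
fuzzyGamma <- function(..., gamma = 0.9) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  .combineFuzzy(.layerList(...), function(m) {
    fsum <- 1 - prod(1 - m)
    fprod <- prod(m)
    fsum^gamma * fprod^(1 - gamma)
  }, sprintf("GAMMA %.2f", gamma))
}

.layerList <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]])) layers <- layers[[1L]]
  layers
}

#' The seven parameter names of the ecological-quality model
#' @return character vector.
#' @export
eqParameterNames <- function() {
  c("population", "lst", "carbon",
    "provisioning", "regulating", "supporting", "cultural")
}

#' Assemble the ecological-quality index
#'
#' Combines exactly the seven named fuzzy-crisp parameter layers —
#' population, LST, carbon flux, and the four ecosystem-function
#' surfaces — into a single EQ membership layer. High membership means
#' deteriorating ecological quality. The GAMMA operator at 0.9 is the
#' default; AND and OR are available for comparison.
#'
#' @param layers named list of seven [FuzzyLayer-class] objects with
#'   names [eqParameterNames()].
#' @param operator `"gamma"`, `"and"` or `"or"`.
#' @param gamma gamma exponent when `operator = "gamma"`.
#' @return a [FuzzyLayer-class].
#' @export
buildEQ <- function(layers, operator = c("gamma", "and", "or"),
                    gamma = 0.9) {
  operator <- match.arg(operator)
  need <- eqParameterNames()
  miss <- setdiff(need, names(layers))
  extra <- setdiff(names(layers), need)
  if (length(miss))
    stop("missing EQ parameter layer(s): ", paste(miss, collapse = ", "))
  if (length(extra))
    stop("unexpected EQ parameter layer(s): ", paste(extra, collapse = ", "))
  layers <- layers[need]
  out <- switch(operator,
                gamma = fuzzyGamma(layers, gamma = gamma),
                and = fuzzyAnd(layers),
                or = fuzzyOr(layers))
  out@source <- paste0("EQ/", out@source)
  out
}

#' Five-level classification of the EQ index
#'
#' Slices the membership surface into the ordered categories very good,
#' good, moderate, bad, very bad (membership near 1 = very bad). With
#' the default equal-interval scheme the breaks are 0.2/0.4/0.6/0.8; the
#' quantile scheme places them at the membership quantiles instead. A
#' value exactly on a break belongs to the upper class.
#'
#' @param eq a [FuzzyLayer-class].
#' @param scheme `"equal"` or `"quantile"`.
#' @param breaks optional custom interior break points (strictly
#'   increasing, inside (0, 1)); overrides `scheme`.
#' @return a [CategoricalRaster-class] with codes 1 ("very good") to
#'   5 ("very bad").
#' @export
classifyEQ <- function(eq, scheme = c("equal", "quantile"), breaks = NULL) {
  scheme <- match.arg(scheme)
  labels <- c("very good", "good", "moderate", "bad", "very bad")
  mu <- rasterValues(eq)
  if (is.null(breaks)) {
    breaks <- if (scheme == "equal") seq(0.2, 0.8, by = 0.2)
              else unname(stats::quantile(mu, probs = seq(0.2, 0.8, 0.2),
                                          na.rm = TRUE))
  }
  if (length(breaks) != 4L || is.unsorted(breaks, strictly = TRUE))
    stop("need 4 strictly increasing interior breaks")
  cls <- matrix(NA_integer_, nrow(mu), ncol(mu))
  ok <- !is.na(mu)
  cls[ok] <- findInterval(mu[ok], breaks) + 1L
  categoricalRaster(cls, grid = gridSpec(eq),
                    legend = stats::setNames(labels, 1:5))
}
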