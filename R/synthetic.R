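# Seed hygiene: every generator runs under .withSeed(), which derives an
# independent stream from (seed, offset) and restores the caller's RNG
# state, so adding a generator call never perturbs another's draws.
.withSeed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) + as.integer(offset))
  expr
}

# Separable Gaussian blur with reflective normalisation at the edges,
# computed as a pair of banded-matrix products.
.gaussKernelMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-(d^2) / (2 * sigma^2))
  K[d > r] <- 0
  K / rowSums(K)
}

.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kr <- .gaussKernelMatrix(nrow(m), sigma)
  Kc <- .gaussKernelMatrix(ncol(m), sigma)
  Kr %*% m %*% t(Kc)
}

#' Land-cover composition of the study conditions
#'
#' Class fractions of the emulated "before" landscape: forest 43.59%,
#' settlement 27.25%, agriculture 20.44%, water 8.72%.
#' @return named numeric vector summing to 1.
#' @export
studyFractions <- function() {
  c(agriculture = 0.2044, forest = 0.4359, settlement = 0.2725,
    water = 0.0872)
}

#' Default class-transition specification
#'
#' Row-stochastic matrix whose forest row moves mass to settlement,
#' water and agriculture in the proportions that reproduce the study
#' conditions' net area changes in expectation (settlement-dominated
#' forest conversion); all other classes are stable.
#' @return 4 x 4 row-stochastic matrix with class-name dimnames.
#' @export
defaultTransitionSpec <- function() {
  cls <- unname(lulcLegend())
  P <- diag(4)
  dimnames(P) <- list(cls, cls)
  P["forest", "agriculture"] <- 142.08 / 24982.31
  P["forest", "settlement"] <- 4725.45 / 24982.31
  P["forest", "water"] <- 620.48 / 24982.31
  P["forest", "forest"] <- 1 - sum(P["forest", -2])
  P
}

.checkStochastic <- function(P) {
  if (any(is.na(P)) || any(P < 0) || any(P > 1) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix must be row-stochastic with entries in [0, 1]")
}

#' Generate a synthetic neutral landscape
#'
#' Builds a categorical raster with target class fractions and spatial
#' autocorrelation: one Gaussian-smoothed random field per class is
#' rank-transformed to a uniform score, additive offsets are calibrated
#' iteratively so the arg-max assignment hits the requested fractions,
#' and each cell takes the class with the highest offset score (ties to
#' the lowest class code). Deterministic given `seed`; realised
#' fractions land within `max(0.02, 3/sqrt(n))` of the targets.
#'
#' @param nrows,ncols grid dimensions.
#' @param fractions named class fractions, summing to 1 (default the
#'   study composition, [studyFractions()]).
#' @param smoothing Gaussian kernel width in cells; 0 gives spatially
#'   independent salt-and-pepper cover. Default 5.
#' @param seed integer seed.
#' @param cellsize cell size in metres (default 10).
#' @param legend legend whose names order the class codes.
#' @return a [CategoricalRaster-class].
#' @examples
#' r <- generateLandscape(60, 60, seed = 1)
#' areaByClass(r)
#' @export
generateLandscape <- function(nrows, ncols, fractions = studyFractions(),
                              smoothing = 5, seed = 1, cellsize = 10,
                              legend = lulcLegend()) {
  fractions <- fractions[match(unname(legend), names(fractions))]
  if (anyNA(fractions) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be named by legend classes, non-negative, sum to 1")
  n <- as.integer(nrows) * as.integer(ncols)
  K <- length(legend)
  tol <- max(0.02, 3 / sqrt(n)) / 2
  U <- .withSeed(seed, 0L, {
    vapply(seq_len(K), function(k) {
      f <- .gaussSmooth(matrix(rnorm(n), nrows, ncols), smoothing)
      rank(as.vector(f), ties.method = "first") / (n + 1)
    }, numeric(n))
  })
  off <- ifelse(fractions > 0, 0, -Inf)
  assign_cells <- function(off) {
    max.col(sweep(U, 2L, off, "+"), ties.method = "first")
  }
  cl <- assign_cells(off)
  for (it in seq_len(400L)) {
    f <- tabulate(cl, nbins = K) / n
    if (max(abs(f - fractions)) < tol) break
    off <- off + (fractions - f)
    off[fractions == 0] <- -Inf
    cl <- assign_cells(off)
  }
  codes <- as.integer(names(legend))
  categoricalRaster(matrix(codes[cl], nrows, ncols),
                    grid = gridSpec2(nrows, ncols, cellsize = cellsize),
                    legend = legend)
}

# Chebyshev distance of every cell to the nearest TRUE cell of `mask`,
# by iterative 8-neighbour dilation.
.chebyshevDistance <- function(mask) {
  d <- matrix(Inf, nrow(mask), ncol(mask))
  d[mask] <- 0
  cur <- mask
  step <- 0L
  dilate <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    out <- m
    for (dr in -1:1) for (dc in -1:1)
      out <- out | p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    out
  }
  while (any(is.infinite(d)) && step < nrow(mask) + ncol(mask)) {
    step <- step + 1L
    cur <- dilate(cur)
    d[cur & is.infinite(d)] <- step
  }
  d
}

#' Apply a known class-transition process to a landscape
#'
#' Produces the "after" raster from a "before" raster under a
#' row-stochastic transition matrix. In `"random"` mode each cell of
#' class i independently draws its new class from row i. In
#' `"frontier"` mode the per-pair quota (row probability times class
#' count, rounded half up) of converting cells is met by converting the
#' class-i cells nearest (Chebyshev distance) to existing class-j
#' cells, emulating settlement expansion at forest edges while keeping
#' exact quota counts.
#'
#' @param lulc a [CategoricalRaster-class].
#' @param P row-stochastic class x class matrix with class-name
#'   dimnames covering every class present (default
#'   [defaultTransitionSpec()]).
#' @param seed integer seed.
#' @param mode `"random"` or `"frontier"`.
#' @return a [CategoricalRaster-class] on the same grid.
#' @export
applyTransition <- function(lulc, P = defaultTransitionSpec(), seed = 1,
                            mode = c("random", "frontier")) {
  mode <- match.arg(mode)
  .checkStochastic(P)
  leg <- classLegend(lulc)
  codes <- as.integer(names(leg))
  present <- unique(as.vector(rasterValues(lulc)))
  present <- present[!is.na(present)]
  if (!all(leg[as.character(present)] %in% rownames(P)))
    stop("transition matrix must cover every class present in the raster")
  v <- rasterValues(lulc)
  out <- v
  .withSeed(seed, 1L, {
    if (mode == "random") {
      for (i in seq_along(codes)) {
        idx <- which(v == codes[i])
        if (!length(idx)) next
        p <- P[leg[i], leg]
        out[idx] <- codes[sample.int(length(codes), length(idx),
                                     replace = TRUE, prob = p)]
      }
    } else {
      converted <- matrix(FALSE, nrow(v), ncol(v))
      for (i in seq_along(codes)) {
        idx_i <- which(v == codes[i] & !is.na(v))
        n_i <- length(idx_i)
        if (!n_i) next
        for (j in seq_along(codes)) {
          if (j == i) next
          p <- P[leg[i], leg[j]]
          q <- floor(p * n_i + 0.5)
          if (q == 0) next
          dmap <- .chebyshevDistance(!is.na(v) & v == codes[j])
          elig <- idx_i[!converted[idx_i]]
          if (!length(elig)) next
          ord <- order(dmap[elig], runif(length(elig)))
          take <- elig[ord][seq_len(min(q, length(elig)))]
          out[take] <- codes[j]
          converted[take] <- TRUE
        }
      }
    }
  })
  categoricalRaster(out, grid = gridSpec(lulc), legend = leg)
}

#' Default covariate specifications
#'
#' Per-class means and standard deviations for the three continuous
#' covariates of the ecological-quality model. The values are
#' synthetic placeholders chosen so class contrasts point the expected
#' way (settlements hotter, denser and higher-emitting than forest);
#' they are configuration, not published coefficients.
#' @return named list of lists with `mean`, `sd` (per class) and `units`.
#' @export
covariateDefaults <- function() {
  list(
    lst = list(
      mean = c(agriculture = 28, forest = 25, settlement = 32, water = 22),
      sd = c(agriculture = 1, forest = 1, settlement = 1, water = 1),
      units = "degC"),
    population = list(
      mean = c(agriculture = 5, forest = 1, settlement = 50, water = 0.5),
      sd = c(agriculture = 1.5, forest = 0.4, settlement = 10,
             water = 0.2),
      units = "persons/cell"),
    carbon = list(
      mean = c(agriculture = 5, forest = 0.5, settlement = 10, water = 1),
      sd = c(agriculture = 1, forest = 0.2, settlement = 2, water = 0.3),
      units = "t/ha")
  )
}

#' Generate a class-correlated continuous covariate
#'
#' Draws each cell from Normal(mean_class, sd_class); nodata cells stay
#' nodata. With all-zero standard deviations the surface is exactly
#' piecewise constant at the class means.
#'
#' @param lulc a [CategoricalRaster-class].
#' @param mean,sd named per-class parameter vectors covering every class
#'   present.
#' @param seed integer seed.
#' @param units unit label for the output raster.
#' @return a [ContinuousRaster-class].
#' @export
generateCovariate <- function(lulc, mean, sd, seed = 1, units = "") {
  leg <- classLegend(lulc)
  v <- rasterValues(lulc)
  present <- leg[as.character(unique(v[!is.na(v)]))]
  if (!all(present %in% names(mean)) || !all(present %in% names(sd)))
    stop("mean/sd must cover every class present: missing ",
         paste(setdiff(present, intersect(names(mean), names(sd))),
               collapse = ", "))
  if (any(sd < 0)) stop("sd must be non-negative")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  .withSeed(seed, 2L, {
    for (code in names(leg)) {
      idx <- which(v == as.integer(code))
      if (!length(idx)) next
      cls <- leg[[code]]
      out[idx] <- stats::rnorm(length(idx), mean[[cls]], sd[[cls]])
    }
  })
  continuousRaster(out, grid = gridSpec(lulc), units = units)
}

#' Sample labelled reference points with a known error rate
#'
#' Samples `n` valid cells without replacement; each point carries the
#' true class and a "mapped" class equal to the truth with probability
#' `1 - error_rate`, otherwise a uniformly chosen wrong class — the
#' uniform-error model under which overall accuracy converges to
#' `1 - error_rate`. Optionally tags an exact 80/20 train/test split.
#'
#' @param truth a [CategoricalRaster-class].
#' @param n number of points.
#' @param error_rate mis-labelling probability in [0, 1).
#' @param seed integer seed.
#' @param split if `TRUE`, add a `split` column with exactly
#'   `round(0.8 n)` `"train"` tags, the rest `"test"`.
#' @return data.frame with columns `x`, `y`, `row`, `col`, `true_code`,
#'   `mapped_code` and optionally `split`.
#' @export
generateReferencePoints <- function(truth, n = 600, error_rate = 0,
                                    seed = 1, split = TRUE) {
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  v <- rasterValues(truth)
  valid <- which(!is.na(v))
  if (n > length(valid))
    stop("n exceeds the number of valid cells")
  grid <- gridSpec(truth)
  codes <- as.integer(names(classLegend(truth)))
  .withSeed(seed, 3L, {
    idx <- sample(valid, n)
    rc <- arrayInd(idx, dim(v))
    true_code <- v[idx]
    mapped <- true_code
    flip <- stats::runif(n) < error_rate
    if (any(flip)) {
      mapped[flip] <- vapply(true_code[flip], function(tc) {
        wrong <- codes[codes != tc]
        wrong[sample.int(length(wrong), 1L)]
      }, integer(1))
    }
    out <- data.frame(
      x = grid@originX + (rc[, 2L] - 0.5) * grid@cellsizeX,
      y = grid@originY - (rc[, 1L] - 0.5) * grid@cellsizeY,
      row = rc[, 1L], col = rc[, 2L],
      true_code = true_code, mapped_code = mapped)
    if (split) {
      ntrain <- round(0.8 * n)
      tags <- rep("test", n)
      tags[sample.int(n, ntrain)] <- "train"
      out$split <- tags
    }
    out
  })
}
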