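test_that("landscape generation is seed-deterministic and fraction-accurate", {
  r1 <- generateLandscape(100, 100, seed = 7)
  r2 <- generateLandscape(100, 100, seed = 7)
  expect_identical(r1@values, r2@values)
  r3 <- generateLandscape(100, 100, seed = 8)
  expect_false(identical(r1@values, r3@values))
  tol <- max(0.02, 3 / 100)
  got <- areaByClass(r1)$percent / 100
  expect_true(all(abs(got - studyFractions()) <= tol))
})

test_that("degenerate fraction vectors behave: single class and validation", {
  r <- generateLandscape(20, 20,
                         fractions = c(agriculture = 0, forest = 1,
                                       settlement = 0, water = 0),
                         seed = 1)
  expect_true(all(rasterValues(r) == 2L))
  expect_error(generateLandscape(10, 10,
                                 fractions = c(forest = 0.7, water = 0.7),
                                 seed = 1),
               "sum to 1")
})

test_that("smoothing produces larger contiguous patches than none", {
  meanPatch <- function(r) {
    v <- rasterValues(r)
    # mean size of 4-connected same-class runs along rows, a cheap
    # monotone proxy for patch size
    runs <- unlist(apply(v, 1, function(row) rle(row)$lengths))
    mean(runs)
  }
  smooth <- generateLandscape(120, 120, smoothing = 5, seed = 3)
  rough <- generateLandscape(120, 120, smoothing = 0, seed = 3)
  expect_gt(meanPatch(smooth), meanPatch(rough))
})

test_that("identity transition returns the input unchanged", {
  r <- generateLandscape(50, 50, seed = 2)
  P <- diag(4); dimnames(P) <- list(names(studyFractions()),
                                    names(studyFractions()))
  dimnames(P) <- list(unname(lulcLegend()), unname(lulcLegend()))
  for (mode in c("random", "frontier"))
    expect_identical(applyTransition(r, P, seed = 5, mode = mode)@values,
                     r@values)
})

test_that("random transitions hit binomial expectations and conserve cells", {
  # 2-class raster, p(forest -> settlement) = 0.5, 10,000 forest cells
  m <- matrix(rep(c(2L, 3L), each = 10000), 100, 200)
  r <- categoricalRaster(m)
  cls <- unname(lulcLegend())
  P <- diag(4); dimnames(P) <- list(cls, cls)
  P["forest", "forest"] <- 0.5; P["forest", "settlement"] <- 0.5
  out <- applyTransition(r, P, seed = 11, mode = "random")
  conv <- mean(rasterValues(out)[m == 2L] == 3L)
  expect_lt(abs(conv - 0.5), 3 * sqrt(0.25 / 10000))
  expect_equal(sum(!is.na(rasterValues(out))), sum(!is.na(m)))
  expect_error(applyTransition(r, P * 2, seed = 1), "stochastic")
})

test_that("frontier mode meets exact quotas at class boundaries", {
  r <- generateLandscape(100, 100, seed = 9)
  P <- defaultTransitionSpec()
  out <- applyTransition(r, P, seed = 9, mode = "frontier")
  n_forest <- sum(rasterValues(r) == 2L)
  for (j in c("agriculture", "settlement", "water")) {
    code <- as.integer(names(which(lulcLegend() == j)))
    got <- sum(rasterValues(r) == 2L & rasterValues(out) == code)
    expect_equal(got, floor(P["forest", j] * n_forest + 0.5))
  }
})

test_that("covariates are class-conditional normals, deterministic by seed", {
  r <- generateLandscape(60, 60, seed = 4)
  spec <- covariateDefaults()$lst
  z1 <- generateCovariate(r, spec$mean, spec$sd, seed = 21)
  z2 <- generateCovariate(r, spec$mean, spec$sd, seed = 21)
  expect_identical(z1@values, z2@values)
  # sd 0 -> exactly the class means
  z0 <- generateCovariate(r, spec$mean, c(agriculture = 0, forest = 0,
                                          settlement = 0, water = 0),
                          seed = 1)
  v <- rasterValues(r)
  expect_true(all(rasterValues(z0)[v == 2L] == spec$mean[["forest"]]))
  # class sample means within 3 sd/sqrt(n)
  for (cls in c("forest", "settlement")) {
    code <- as.integer(names(which(lulcLegend() == cls)))
    idx <- which(v == code)
    expect_lt(abs(mean(rasterValues(z1)[idx]) - spec$mean[[cls]]),
              3 * spec$sd[[cls]] / sqrt(length(idx)))
  }
  expect_error(generateCovariate(r, c(forest = 1), c(forest = 1)),
               "cover every class")
})

test_that("reference points carry the designed error structure and split", {
  r <- generateLandscape(80, 80, seed = 6)
  pts <- generateReferencePoints(r, n = 600, error_rate = 0, seed = 13)
  expect_equal(nrow(pts), 600)
  expect_true(all(pts$true_code == pts$mapped_code))
  expect_equal(sum(pts$split == "train"), 480)
  expect_equal(sum(pts$split == "test"), 120)
  # points index the truth raster correctly
  v <- rasterValues(r)
  expect_true(all(v[cbind(pts$row, pts$col)] == pts$true_code))
  big <- generateReferencePoints(r, n = 5000, error_rate = 0.1, seed = 13)
  oa <- mean(big$true_code == big$mapped_code)
  expect_lt(abs(oa - 0.9), 3 * sqrt(0.09 / 5000))
  expect_error(generateReferencePoints(r, n = 1e6, seed = 1), "exceeds")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(generateLandscape(20, 20, seed = 99))
  expect_identical(runif(1), before)
})
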