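test_that("sigmoid memberships hit their anchor points", {
  r <- continuousRaster(matrix(c(10, 30, 60), 1))
  lg <- fuzzify(r, "large", midpoint = 30, spread = 5)
  sm <- fuzzify(r, "small", midpoint = 30, spread = 5)
  expect_equal(rasterValues(lg)[1, 2], 0.5)        # x = m -> 0.5
  expect_equal(rasterValues(sm)[1, 2], 0.5)
  expect_equal(rasterValues(lg)[1, 3], 1 / (1 + 2^-5))   # 0.9697
  # small + large with equal parameters partition unity
  expect_equal(rasterValues(lg) + rasterValues(sm),
               matrix(1, 1, 3))
  # strictly monotone and 0.5-crossing only at m
  x <- continuousRaster(matrix(seq(1, 100, length.out = 50), 1))
  mu <- as.vector(rasterValues(fuzzify(x, "large", midpoint = 50,
                                       spread = 3)))
  expect_true(all(diff(mu) > 0))
  expect_error(fuzzify(continuousRaster(matrix(c(-1, 2), 1)), "small",
                       midpoint = 1), "positive")
})

test_that("linear memberships ramp and clamp", {
  r <- continuousRaster(matrix(c(-5, 0, 5, 10, 15), 1))
  up <- rasterValues(fuzzify(r, "linear_large", bounds = c(0, 10)))
  expect_equal(as.vector(up), c(0, 0, 0.5, 1, 1))
  down <- rasterValues(fuzzify(r, "linear_small", bounds = c(0, 10)))
  expect_equal(as.vector(up + down), rep(1, 5))
})

test_that("AND/OR are cell-wise min/max and bracket every input", {
  a <- constantFuzzy(0.2); b <- constantFuzzy(0.7)
  expect_layer_equal(fuzzyAnd(a, b), 0.2)
  expect_layer_equal(fuzzyOr(a, b), 0.7)
  expect_layer_equal(fuzzyAnd(a, a), 0.2)
  set.seed(53)
  xs <- lapply(1:3, function(i)
    fuzzify(continuousRaster(matrix(runif(64), 8)), "linear_large",
            bounds = c(0, 1)))
  lo <- rasterValues(fuzzyAnd(xs)); hi <- rasterValues(fuzzyOr(xs))
  for (x in xs) {
    expect_true(all(rasterValues(x) >= lo))
    expect_true(all(rasterValues(x) <= hi))
  }
})

test_that("gamma operator matches its formula and limiting cases", {
  a <- constantFuzzy(0.5)
  expect_layer_equal(fuzzyGamma(a, a, gamma = 0.9),
                     0.75^0.9 * 0.25^0.1, tol = 1e-12)
  expect_equal(round(rasterValues(fuzzyGamma(a, a, gamma = 0.9))[1], 3),
               0.672)
  b <- constantFuzzy(0.3)
  expect_layer_equal(fuzzyGamma(a, b, gamma = 1), 1 - 0.5 * 0.7)  # alg. sum
  expect_layer_equal(fuzzyGamma(a, b, gamma = 0), 0.15)           # product
  zero <- constantFuzzy(0); one <- constantFuzzy(1)
  expect_layer_equal(fuzzyGamma(zero, b, gamma = 0.9), 0)
  expect_layer_equal(fuzzyGamma(one, one, gamma = 0.9), 1)
  expect_error(fuzzyGamma(a, b, gamma = 1.2), "gamma")
})

test_that("gamma output is bounded, symmetric and between product and sum", {
  set.seed(59)
  layers <- lapply(1:4, function(i)
    fuzzify(continuousRaster(matrix(runif(100), 10)), "linear_large",
            bounds = c(0, 1)))
  for (g in c(0, 0.25, 0.5, 0.9, 1)) {
    out <- rasterValues(fuzzyGamma(layers, gamma = g))
    expect_true(all(out >= 0 & out <= 1))
    arr <- simplify2array(lapply(layers, rasterValues))
    fprod <- apply(arr, c(1, 2), prod)
    fsum <- 1 - apply(1 - arr, c(1, 2), prod)
    expect_true(all(out >= fprod - 1e-12 & out <= fsum + 1e-12))
  }
  perm <- rasterValues(fuzzyGamma(rev(layers), gamma = 0.9))
  expect_equal(perm, rasterValues(fuzzyGamma(layers, gamma = 0.9)))
})

test_that("EQ assembly demands the seven named layers and is monotone", {
  mk <- function(v) constantFuzzy(v, 4, 4)
  layers <- setNames(lapply(rep(0.4, 7), mk), eqParameterNames())
  eq <- buildEQ(layers)
  expect_true(all(rasterValues(eq) >= 0 & rasterValues(eq) <= 1))
  expect_error(buildEQ(layers[-1]), "missing.*population")
  extra <- c(layers, list(junk = mk(0.1)))
  expect_error(buildEQ(extra), "unexpected")
  # all-zero -> 0 (best), all-one -> 1 (worst)
  expect_layer_equal(buildEQ(setNames(lapply(rep(0, 7), mk),
                                      eqParameterNames())), 0)
  expect_layer_equal(buildEQ(setNames(lapply(rep(1, 7), mk),
                                      eqParameterNames())), 1)
  # raising any one input never decreases EQ (gamma is monotone)
  base <- rasterValues(eq)[1, 1]
  for (nm in eqParameterNames()) {
    bumped <- layers
    bumped[[nm]] <- mk(0.8)
    expect_gte(rasterValues(buildEQ(bumped))[1, 1], base)
  }
})

test_that("EQ classification uses upper-class boundaries and is monotone", {
  mus <- c(0.05, 0.2, 0.39, 0.4, 0.61, 0.8, 0.95, 1.0)
  eq <- fuzzify(continuousRaster(matrix(mus, 1)), "linear_large",
                bounds = c(0, 1))
  cls <- classifyEQ(eq)
  expect_equal(as.vector(rasterValues(cls)), c(1L, 2L, 2L, 3L, 4L, 5L, 5L, 5L))
  expect_equal(unname(classLegend(cls)[c("1", "5")]),
               c("very good", "very bad"))
  expect_true(all(diff(as.vector(rasterValues(cls))) >= 0))
  # quantile scheme balances the classes on a spread-out surface
  set.seed(61)
  big <- fuzzify(continuousRaster(matrix(runif(2500), 50)), "linear_large",
                 bounds = c(0, 1))
  q <- table(rasterValues(classifyEQ(big, scheme = "quantile")))
  expect_true(max(q) - min(q) <= 5)
})
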