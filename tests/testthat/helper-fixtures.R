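# Shared fixtures: the published area tables of the worked example and
# small hand-built rasters.

areas2017 <- function() {
  areaTable(agriculture = 11711.33, forest = 24982.31,
            settlement = 15614, water = 4999.61)
}

areas2021 <- function() {
  areaTable(agriculture = 11853.41, forest = 19494.3,
            settlement = 20339.45, water = 5620.09)
}

# constant fuzzy layer built through the linear ramp (exact values)
constantFuzzy <- function(value, nrows = 2, ncols = 2) {
  fuzzify(continuousRaster(matrix(value, nrows, ncols)),
          "linear_large", bounds = c(0, 1))
}

expect_layer_equal <- function(layer, expected, tol = 1e-12) {
  expect_equal(as.vector(rasterValues(layer)), rep_len(expected,
               prod(dim(rasterValues(layer)))), tolerance = tol)
}
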