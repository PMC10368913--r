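test_that("ASCII grid round-trip is the identity for categorical rasters", {
  m <- matrix(sample(1:4, 30, replace = TRUE), 5, 6)
  r <- categoricalRaster(m, grid = gridSpec2(5, 6, cellsize = 10,
                                             origin = c(100, 900)))
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(r, p)
  r2 <- readAsciiGrid(p, "categorical")
  expect_identical(r2@values, r@values)
  expect_true(isTRUE(ecoscape:::.gridsAligned(gridSpec(r), gridSpec(r2))))
})

test_that("continuous round-trip preserves values within 1e-6 relative", {
  m <- matrix(runif(100) * 1000, 10, 10)
  r <- continuousRaster(m, grid = gridSpec2(10, 10))
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(r, p)
  expect_equal(rasterValues(readAsciiGrid(p, "continuous")), m,
               tolerance = 1e-6)
})

test_that("nodata cells survive a round trip and are excluded from areas", {
  m <- matrix(2L, 3, 3)
  m[c(1, 5, 9)] <- NA
  r <- categoricalRaster(m)
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(r, p)
  r2 <- readAsciiGrid(p, "categorical")
  expect_identical(is.na(rasterValues(r2)), is.na(m))
  ab <- areaByClass(r2)
  expect_equal(ab$cells[ab$class == "forest"], 6L)
  expect_equal(attr(ab, "total_area_ha"), 6 * 0.01)
})

test_that("reading a hand-written grid with a NODATA cell works", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -9999",
               "2 2 2", "2 -9999 2", "2 2 2"), p)
  r <- readAsciiGrid(p, "categorical")
  expect_equal(sum(!is.na(rasterValues(r))), 8L)
  expect_error(readAsciiGrid(p, "categorical", legend = c(`9` = "x")),
               "legend")
})

test_that("categorical reader rejects fractional cell values", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -9999", "1 1.5"), p)
  expect_error(readAsciiGrid(p, "categorical"), "non-integer")
})

test_that("alignment check passes identical grids and names the offender", {
  a <- categoricalRaster(matrix(1L, 4, 4))
  b <- categoricalRaster(matrix(2L, 4, 4))
  expect_true(assertAligned(a, b))
  coarse <- categoricalRaster(matrix(1L, 4, 4),
                              grid = gridSpec2(4, 4, cellsize = 30))
  expect_error(assertAligned(a, coarse = coarse), "coarse.*cellsize")
  shifted <- categoricalRaster(matrix(1L, 4, 4),
                               grid = gridSpec2(4, 4, origin = c(5, 0)))
  expect_error(assertAligned(a, shifted = shifted), "origin")
})

test_that("area accounting is exact, conserving and position-invariant", {
  m <- matrix(c(rep(1L, 25), rep(2L, 40), rep(3L, 20), rep(4L, 15)), 10, 10)
  r <- categoricalRaster(m)
  ab <- areaByClass(r)
  expect_equal(ab$area_ha, c(0.25, 0.40, 0.20, 0.15))
  expect_equal(sum(ab$area_ha), attr(ab, "total_area_ha"))
  expect_equal(sum(ab$percent), 100)
  # shuffling cell positions changes nothing (pure counting)
  perm <- matrix(sample(as.vector(m)), 10, 10)
  expect_equal(areaByClass(categoricalRaster(perm))$area_ha, ab$area_ha)
  # 100 cells of one class at 10 m -> 1 ha
  expect_equal(areaByClass(categoricalRaster(matrix(2L, 10, 10)))$area_ha[2],
               1)
})

test_that("all-nodata rasters and invalid grids are rejected", {
  m <- matrix(NA_integer_, 2, 2)
  expect_error(areaByClass(categoricalRaster(m)), "no valid cells")
  expect_error(gridSpec2(0, 5), "positive")
  expect_error(categoricalRaster(matrix(9L, 2, 2)), "legend")
})

test_that("typed-in area tables mirror the raster-derived layout", {
  a <- areaTable(agriculture = 2, forest = 1, settlement = 0, water = 1)
  expect_equal(a$percent, c(50, 25, 0, 25))
  expect_equal(a$code, 1:4)
  expect_error(areaTable(3, 1), "named")
})
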