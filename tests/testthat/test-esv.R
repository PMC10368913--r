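test_that("default coefficient table has the expected structure", {
  tab <- esvCoefficients()
  expect_equal(nrow(tab), 16)
  expect_equal(names(tab)[-(1:2)],
               c("agriculture", "forest", "settlement", "water"))
  expect_equal(unname(colSums(tab[, -(1:2)])), c(92, 971, 0, 8498))
  expect_equal(unname(table(tab$group)[c("provisioning", "regulating",
                                         "supporting", "cultural")]),
               c(2L, 6L, 6L, 2L), ignore_attr = TRUE)
})

test_that("coefficient table round-trips through delimited text", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeCoefficientTable(esvCoefficients(), p)
  expect_equal(readCoefficientTable(p), esvCoefficients())
})

test_that("single-hectare valuations match the coefficient column sums", {
  a <- areaTable(agriculture = 1, forest = 0, settlement = 0, water = 0)
  expect_equal(esvByClass(a)$esv_musd[1] * 1e6, 92)   # 54 + 14 + 24 US$
  s <- areaTable(agriculture = 0, forest = 0, settlement = 12345, water = 0)
  expect_equal(esvByClass(s)$esv_musd[3], 0)
  zero <- areaTable(agriculture = 0, forest = 0, settlement = 0, water = 0)
  expect_equal(totalEsv(zero), 0)
})

test_that("class, function and group totals conserve exactly", {
  set.seed(41)
  for (i in 1:10) {
    coeffs <- esvCoefficients()
    coeffs[, 3:6] <- matrix(runif(64, 0, 500), 16)
    a <- areaTable(agriculture = runif(1, 0, 1e4), forest = runif(1, 0, 1e4),
                   settlement = runif(1, 0, 1e4), water = runif(1, 0, 1e4))
    k <- sum(esvByClass(a, coeffs)$esv_musd)
    f <- sum(esvByFunction(a, coeffs)$esv_musd)
    g <- sum(esvByGroup(a, coeffs)$esv_musd)
    expect_equal(f, k, tolerance = 1e-12)
    expect_equal(g, k, tolerance = 1e-12)
  }
})

test_that("valuation is linear in areas and additive across splits", {
  a <- areas2017()
  doubled <- areaTable(agriculture = 2 * 11711.33, forest = 2 * 24982.31,
                       settlement = 2 * 15614, water = 2 * 4999.61)
  expect_equal(esvByClass(doubled)$esv_musd, 2 * esvByClass(a)$esv_musd)
  half <- areaTable(agriculture = 11711.33 / 2, forest = 24982.31 / 2,
                    settlement = 15614 / 2, water = 4999.61 / 2)
  expect_equal(2 * totalEsv(half), totalEsv(a))
})

test_that("change analysis uses unrounded baselines and flags zero rows", {
  r0 <- esvReport(areas2017())
  r1 <- esvReport(areas2021())
  ch <- esvChange(r0, r1)
  expect_true(is.na(ch$by_class$change_pct[3]))   # settlement 0 baseline
  same <- esvChange(r0, r0)
  expect_true(all(same$by_class$change_musd == 0))
  expect_true(all(same$by_function$change_musd == 0))
})

test_that("sensitivity equals the analytic share ESV_k/ESV for any delta", {
  for (a in list(areas2017(), areas2021())) {
    total <- totalEsv(a)
    k <- esvByClass(a)
    for (cls in c("agriculture", "forest", "water")) {
      share <- k$esv_musd[k$class == cls] / total
      for (d in c(-0.5, -0.1, 0.1, 0.5)) {
        cs <- sensitivityCS(a, class = cls, delta = d)
        expect_equal(cs$cs, share, tolerance = 1e-12)
        expect_equal(cs$verdict, "inelastic")
      }
    }
    und <- sensitivityCS(a, class = "settlement")
    expect_true(is.na(und$cs))
    expect_equal(und$verdict, "undefined")
  }
})

test_that("function-value surfaces conserve the group subtotals", {
  r <- generateLandscape(50, 50, seed = 44)
  ab <- areaByClass(r)
  for (g in c("provisioning", "regulating", "supporting", "cultural")) {
    surf <- esvSurface(r, group = g)
    expect_equal(sum(rasterValues(surf), na.rm = TRUE) / 1e6,
                 esvByGroup(ab)$esv_musd[esvByGroup(ab)$group == g],
                 tolerance = 1e-12)
  }
  # constant raster: provisioning on all-forest = (43+138) * 0.01 ha/cell
  forest <- categoricalRaster(matrix(2L, 5, 5))
  expect_equal(unique(as.vector(rasterValues(
    esvSurface(forest, group = "provisioning")))), 181 * 0.01)
  sett <- categoricalRaster(matrix(3L, 5, 5))
  for (g in c("provisioning", "regulating", "supporting", "cultural"))
    expect_true(all(rasterValues(esvSurface(sett, group = g)) == 0))
})

test_that("reports refuse classes without coefficients", {
  a <- areaTable(agriculture = 1, forest = 1)
  expect_error(esvByClass(a), "no area given")
})
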