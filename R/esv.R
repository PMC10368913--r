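#' Default benefit-transfer value-coefficient table
#'
#' Per-hectare annual value coefficients `VC_kf` (US$/ha/yr) for 16
#' ecosystem-service functions across the four land-cover classes,
#' grouped into provisioning, regulating, supporting and cultural
#' services. Agriculture, forest, settlement and water are matched to
#' the farmland, forest, urban and wetland biomes of the global
#' benefit-transfer literature. The table is a replaceable input: any
#' file in the same layout can stand in via [readCoefficientTable()].
#'
#' @return data.frame with columns `service`, `group`, `agriculture`,
#'   `forest`, `settlement`, `water`.
#' @examples
#' colSums(esvCoefficients()[, -(1:2)])   # 92, 971, 0, 8498 US$/ha/yr
#' @export
esvCoefficients <- function() {
  tab <- read.csv(text = "service,group,agriculture,forest,settlement,water
food production,provisioning,54,43,0,41
raw material,provisioning,0,138,0,0
gas regulation,regulating,0,0,0,0
climate regulation,regulating,0,141,0,0
disturbance regulation,regulating,0,2,0,0
water regulation,regulating,0,2,0,5445
water supply,regulating,0,3,0,2117
waste treatment,regulating,0,87,0,665
soil formation and retention,supporting,0,10,0,0
nutrient cycling,supporting,0,361,0,0
erosion control,supporting,0,96,0,0
pollination,supporting,14,0,0,0
biodiversity,supporting,24,2,0,0
genetic resources,supporting,0,16,0,0
recreation and tourism,cultural,0,68,0,230
cultural,cultural,0,2,0,0
", stringsAsFactors = FALSE, check.names = FALSE)
  tab
}

#' Read / write a value-coefficient table
#'
#' Delimited text with a `service` column, a `group` column
#' (provisioning/regulating/supporting/cultural) and one numeric column
#' per land-cover class.
#'
#' @param path file path.
#' @return `readCoefficientTable()`: the validated data.frame;
#'   `writeCoefficientTable()`: `path`, invisibly.
#' @export
readCoefficientTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .coeffMatrix(tab)  # validates
  tab
}

#' @rdname readCoefficientTable
#' @param coeffs coefficient data.frame.
#' @export
writeCoefficientTable <- function(coeffs, path) {
  utils::write.csv(coeffs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.esvGroups <- c("provisioning", "regulating", "supporting", "cultural")

# coefficient data.frame -> validated numeric matrix (functions x classes)
.coeffMatrix <- function(coeffs) {
  if (!all(c("service", "group") %in% names(coeffs)))
    stop("coefficient table needs 'service' and 'group' columns")
  cls <- setdiff(names(coeffs), c("service", "group"))
  m <- as.matrix(coeffs[, cls, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- coeffs$service
  if (any(m < 0)) stop("value coefficients must be non-negative")
  if (!all(coeffs$group %in% .esvGroups))
    stop("groups must be one of: ", paste(.esvGroups, collapse = ", "))
  attr(m, "group") <- coeffs$group
  m
}

# areas input (areaByClass()/areaTable() data.frame or named vector)
# -> named vector of hectares in coefficient-table class order
.areasVector <- function(areas, classes) {
  a <- if (is.data.frame(areas)) {
    stats::setNames(areas$area_ha, areas$class)
  } else areas
  miss <- setdiff(classes, names(a))
  if (length(miss))
    stop("no area given for class(es): ", paste(miss, collapse = ", "))
  a[classes]
}

#' Ecosystem-service value per land-cover class
#'
#' Benefit transfer over the class areas:
#' \eqn{ESV_k = \sum_f A_k \, VC_{kf} = A_k \sum_f VC_{kf}},
#' reported in million US$/yr.
#'
#' @param areas per-class areas in hectares: the data.frame of
#'   [areaByClass()] / [areaTable()], or a named numeric vector.
#' @param coeffs coefficient table (default [esvCoefficients()]).
#' @return data.frame with columns `class`, `area_ha`, `esv_musd`.
#' @examples
#' a2017 <- areaTable(agriculture = 11711.33, forest = 24982.31,
#'                    settlement = 15614, water = 4999.61)
#' esvByClass(a2017)
#' @export
esvByClass <- function(areas, coeffs = esvCoefficients()) {
  m <- .coeffMatrix(coeffs)
  a <- .areasVector(areas, colnames(m))
  data.frame(class = colnames(m), area_ha = unname(a),
             esv_musd = unname(a * colSums(m)) / 1e6)
}

#' Ecosystem-service value per service function
#'
#' \eqn{ESV_f = \sum_k A_k \, VC_{kf}} for each of the 16 functions,
#' in million US$/yr, with the function's group tag carried along.
#'
#' @inheritParams esvByClass
#' @return data.frame with columns `service`, `group`, `esv_musd`.
#' @export
esvByFunction <- function(areas, coeffs = esvCoefficients()) {
  m <- .coeffMatrix(coeffs)
  a <- .areasVector(areas, colnames(m))
  data.frame(service = rownames(m), group = attr(m, "group"),
             esv_musd = unname(m %*% a)[, 1L] / 1e6)
}

#' Group subtotals of the per-function values
#' @inheritParams esvByClass
#' @return data.frame with columns `group`, `esv_musd` in the fixed
#'   provisioning/regulating/supporting/cultural order.
#' @export
esvByGroup <- function(areas, coeffs = esvCoefficients()) {
  f <- esvByFunction(areas, coeffs)
  agg <- tapply(f$esv_musd, factor(f$group, levels = .esvGroups), sum)
  data.frame(group = names(agg), esv_musd = as.numeric(agg))
}

#' Total ecosystem-service value
#'
#' \eqn{ESV = \sum_f \sum_k A_k VC_{kf}}, equal to both the class-wise
#' and the function-wise sums. `rounded = TRUE` returns the
#' round-then-sum total — each class value rounded half-up to 2 decimal
#' places before summation — the convention under which published class
#' tables add up exactly.
#'
#' @inheritParams esvByClass
#' @param rounded return the round-then-sum total (default `FALSE`:
#'   full precision).
#' @return total value in million US$/yr.
#' @export
totalEsv <- function(areas, coeffs = esvCoefficients(), rounded = FALSE) {
  k <- esvByClass(areas, coeffs)$esv_musd
  if (rounded) sum(.round2(k)) else sum(k)
}

# round half up to 2 decimals (round() rounds half to even)
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Full valuation report for one date
#'
#' Bundles class, function and group values plus both total
#' conventions; the unrounded class-wise and function-wise totals agree
#' to 1e-9 relative by construction and this identity is asserted.
#'
#' @inheritParams esvByClass
#' @param label optional date/scenario label.
#' @return an object of class `ESVReport`: a list with `by_class`,
#'   `by_function`, `by_group`, `total`, `total_rounded`, `label`.
#' @export
esvReport <- function(areas, coeffs = esvCoefficients(), label = "") {
  k <- esvByClass(areas, coeffs)
  f <- esvByFunction(areas, coeffs)
  g <- esvByGroup(areas, coeffs)
  tk <- sum(k$esv_musd); tf <- sum(f$esv_musd)
  if (tk > 0 && abs(tk - tf) / tk > 1e-9)
    stop("internal conservation failure: class and function totals differ")
  structure(list(by_class = k, by_function = f, by_group = g,
                 total = tk, total_rounded = sum(.round2(k$esv_musd)),
                 label = label),
            class = "ESVReport")
}

#' @export
print.ESVReport <- function(x, ...) {
  cat(sprintf("ESV report%s\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  k <- x$by_class
  for (i in seq_len(nrow(k)))
    cat(sprintf("  %-12s %10.2f ha  %6.2f M US$/yr\n",
                k$class[i], k$area_ha[i], .round2(k$esv_musd[i])))
  cat(sprintf("  total %.2f M US$/yr (round-then-sum %.2f)\n",
              x$total, x$total_rounded))
  invisible(x)
}

#' Change in ecosystem-service value between two dates
#'
#' Absolute (million US$) and percent changes per class and per
#' function, with the percent base being the *unrounded* first-date
#' value. Zero-baseline rows report `NA` percent, never infinities.
#'
#' @param report0,report1 two [esvReport()] objects built with the same
#'   coefficient table.
#' @return list with data.frames `by_class` and `by_function`, each
#'   carrying `esv0_musd`, `esv1_musd`, `change_musd`, `change_pct`.
#' @export
esvChange <- function(report0, report1) {
  if (!identical(report0$by_class$class, report1$by_class$class) ||
      !identical(report0$by_function$service, report1$by_function$service))
    stop("reports must share class and function sets")
  chg <- function(v0, v1) {
    data.frame(esv0_musd = v0, esv1_musd = v1, change_musd = v1 - v0,
               change_pct = ifelse(v0 != 0, 100 * (v1 - v0) / v0, NA_real_))
  }
  bc <- cbind(report0$by_class["class"],
              chg(report0$by_class$esv_musd, report1$by_class$esv_musd))
  bf <- cbind(report0$by_function[c("service", "group")],
              chg(report0$by_function$esv_musd,
                  report1$by_function$esv_musd))
  list(by_class = bc, by_function = bf)
}

#' Coefficient of sensitivity (elasticity) of the total ESV
#'
#' Scales the value-coefficient column of one class by `1 + delta`
#' (default the customary 50% adjustment) and measures the elasticity
#' of the total value:
#' \deqn{CS = \frac{(ESV_j - ESV_i)/ESV_i}{(VC_{jk} - VC_{ik})/VC_{ik}}}
#' A class is *elastic* when CS > 1 and *inelastic* when CS < 1. For
#' this linear valuation CS reduces analytically to
#' \eqn{ESV_k / ESV}, independent of the size and sign of the
#' adjustment; both signs are computed and their agreement to 1e-12
#' relative is asserted. An all-zero coefficient column leaves CS
#' undefined and is reported as such (`NA` with verdict
#' `"undefined"`).
#'
#' @inheritParams esvByClass
#' @param class class whose coefficient column is perturbed.
#' @param delta adjustment fraction (default 0.5 = 50%).
#' @return data.frame with `class`, `delta`, `esv_i`, `esv_j` (US$),
#'   `cs` and `verdict` (`"elastic"`, `"inelastic"` or `"undefined"`).
#' @export
sensitivityCS <- function(areas, coeffs = esvCoefficients(), class,
                          delta = 0.5) {
  m <- .coeffMatrix(coeffs)
  if (!class %in% colnames(m)) stop("unknown class: ", class)
  a <- .areasVector(areas, colnames(m))
  esv_i <- sum(a * colSums(m))
  if (esv_i <= 0) stop("baseline total ESV must be positive")
  if (all(m[, class] == 0))
    return(data.frame(class = class, delta = delta, esv_i = esv_i,
                      esv_j = NA_real_, cs = NA_real_,
                      verdict = "undefined"))
  cs_at <- function(d) {
    m2 <- m
    m2[, class] <- m2[, class] * (1 + d)
    esv_j <- sum(a * colSums(m2))
    ((esv_j - esv_i) / esv_i) / d
  }
  cs_pos <- cs_at(abs(delta)); cs_neg <- cs_at(-abs(delta))
  if (abs(cs_pos - cs_neg) > 1e-12 * max(abs(cs_pos), 1))
    stop("sensitivity not sign-symmetric: linear-model identity violated")
  m2 <- m; m2[, class] <- m2[, class] * (1 + delta)
  data.frame(class = class, delta = delta, esv_i = esv_i,
             esv_j = sum(a * colSums(m2)), cs = cs_pos,
             verdict = if (cs_pos > 1) "elastic" else "inelastic")
}

#' Per-pixel ecosystem-function value surface
#'
#' Converts a LULC map into a continuous surface of one service group's
#' value: each cell gets \eqn{\sum_{f \in group} VC_{kf}} for its class
#' k, times the cell area in hectares (US$/cell/yr). Summing a group
#' surface over all valid cells reproduces that group's subtotal from
#' [esvByGroup()] on the same raster. These four surfaces are the
#' ecosystem-function parameters entering the fuzzy EQ model.
#'
#' @param lulc a [CategoricalRaster-class].
#' @param coeffs coefficient table.
#' @param group one of `"provisioning"`, `"regulating"`, `"supporting"`,
#'   `"cultural"`.
#' @return a [ContinuousRaster-class] in US$/cell/yr; nodata propagates.
#' @export
esvSurface <- function(lulc, coeffs = esvCoefficients(),
                       group = .esvGroups) {
  group <- match.arg(group)
  m <- .coeffMatrix(coeffs)
  colSumsGroup <- colSums(m[attr(m, "group") == group, , drop = FALSE])
  leg <- classLegend(lulc)
  if (!all(leg %in% colnames(m)))
    stop("coefficient table lacks class(es): ",
         paste(setdiff(leg, colnames(m)), collapse = ", "))
  v <- rasterValues(lulc)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  perCell <- .cellAreaHa(gridSpec(lulc))
  for (code in names(leg))
    out[which(v == as.integer(code))] <- colSumsGroup[[leg[[code]]]] * perCell
  continuousRaster(out, grid = gridSpec(lulc), units = "US$/cell/yr")
}
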