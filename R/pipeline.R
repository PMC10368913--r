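#' Valuation tables and sensitivity for two dates
#'
#' One-call reproduction of the benefit-transfer worked example: from
#' two per-class area tables it writes (i) a class-wise valuation table
#' with absolute and percent changes, (ii) the function-wise analogue
#' with group subtotals, and (iii) the coefficient-sensitivity results
#' for every class at both dates. The class/function conservation
#' identity is asserted before anything is written.
#'
#' @param areas0,areas1 per-class areas (see [esvByClass()]) for the
#'   earlier and later date.
#' @param coeffs coefficient table (default [esvCoefficients()]).
#' @param outdir output directory, created if needed; `NULL` skips
#'   writing.
#' @param labels length-2 date labels used in messages and file
#'   headers.
#' @param delta sensitivity adjustment fraction (default 0.5).
#' @return invisibly, a list with `report0`, `report1`, `change`,
#'   `sensitivity` and the written file paths.
#' @export
runEsvTables <- function(areas0, areas1, coeffs = esvCoefficients(),
                         outdir = NULL, labels = c("t0", "t1"),
                         delta = 0.5) {
  r0 <- esvReport(areas0, coeffs, label = labels[1L])
  r1 <- esvReport(areas1, coeffs, label = labels[2L])
  chg <- esvChange(r0, r1)
  cls <- r0$by_class$class
  sens <- do.call(rbind, lapply(seq_along(labels), function(i) {
    areas <- if (i == 1L) areas0 else areas1
    out <- do.call(rbind, lapply(cls, function(k)
      sensitivityCS(areas, coeffs, class = k, delta = delta)))
    cbind(date = labels[i], out)
  }))
  files <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(outdir, c("esv_by_class.csv", "esv_by_function.csv",
                                 "esv_sensitivity.csv"))
    utils::write.csv(chg$by_class, files[1L], row.names = FALSE)
    utils::write.csv(chg$by_function, files[2L], row.names = FALSE)
    utils::write.csv(sens, files[3L], row.names = FALSE)
  }
  invisible(list(report0 = r0, report1 = r1, change = chg,
                 sensitivity = sens, files = files))
}

#' Demo run configuration
#'
#' The bundled configuration for a fully synthetic end-to-end run: a
#' 200 x 200 landscape at 10 m with the study composition, a
#' frontier-mode forest-to-settlement transition, the default covariate
#' specifications, 600 reference points with a 5% labelling error, and
#' the GAMMA-0.9 ecological-quality model.
#'
#' @param seed root seed.
#' @return a nested configuration list accepted by [runFull()].
#' @export
demoConfig <- function(seed = 42) {
  list(
    seed = seed,
    synthesis = list(
      nrows = 200, ncols = 200, cellsize = 10,
      fractions = as.list(studyFractions()),
      smoothing = 5,
      transition = defaultTransitionSpec(),
      mode = "frontier",
      covariates = covariateDefaults(),
      reference = list(n = 600, error_rate = 0.05)
    ),
    membership = list(functions = "linear_small", covariates = "large",
                      spread = 5),
    combine = list(operator = "gamma", gamma = 0.9)
  )
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension) with the same schema as [demoConfig()];
#' either a `synthesis` block or an `inputs` block (paths to the two
#' LULC grids and the per-date covariate grids) must be present —
#' exactly one of the two.
#'
#' @param path configuration file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg
}

.validateConfig <- function(config) {
  has_syn <- !is.null(config$synthesis)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp)
    stop("config must contain exactly one of 'synthesis' or 'inputs'")
  if (has_inp) {
    need <- c("t0", "t1")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("inputs block missing: ", paste(miss, collapse = ", "))
    for (nm in c("lst", "population", "carbon")) {
      if (is.null(config$inputs$covariates[[nm]]))
        stop("inputs block missing covariate '", nm, "'")
    }
    paths <- c(unlist(config$inputs[need]),
               unlist(config$inputs$covariates))
    bad <- paths[!file.exists(paths)]
    if (length(bad)) stop("input file(s) not found: ",
                          paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# fuzzify one raw parameter layer per pipeline policy; sigmoid layers
# containing non-positive values are shifted positive (logged).
.pipeFuzzify <- function(layer, shape, spread, log) {
  if (shape %in% c("small", "large")) {
    v <- rasterValues(layer)
    lo <- min(v, na.rm = TRUE)
    if (lo <= 0) {
      shift <- -lo + 1e-6 * max(1, diff(range(v, na.rm = TRUE)))
      log(sprintf("shifting layer by %+.4g before sigmoid '%s' (min %.4g <= 0)",
                  shift, shape, lo))
      layer <- continuousRaster(v + shift, grid = gridSpec(layer),
                                units = layer@units)
    }
  }
  suppressMessages(fuzzify(layer, shape = shape, spread = spread))
}

.eqForDate <- function(lulc, covs, coeffs, membership, combine, log) {
  groups <- .esvGroups
  layers <- c(
    stats::setNames(lapply(names(covs), function(nm)
      .pipeFuzzify(covs[[nm]], membership$covariates %||% "large",
                   membership$spread %||% 5, log)), names(covs)),
    stats::setNames(lapply(groups, function(g)
      .pipeFuzzify(esvSurface(lulc, coeffs, group = g),
                   membership$functions %||% "linear_small",
                   membership$spread %||% 5, log)), groups)
  )
  buildEQ(layers, operator = combine$operator %||% "gamma",
          gamma = combine$gamma %||% 0.9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept a transition spec as a matrix, a data.frame with class
# rownames, or the named list-of-rows form YAML/JSON configs produce
.asTransitionSpec <- function(P) {
  if (is.matrix(P)) return(P)
  if (is.data.frame(P)) {
    m <- as.matrix(P)
    if (is.null(rownames(m)) || any(rownames(m) == ""))
      rownames(m) <- colnames(m)
    return(m)
  }
  if (is.list(P)) {
    m <- do.call(rbind, lapply(P, function(row) unlist(row)))
    rownames(m) <- names(P)
    return(m[, rownames(m), drop = FALSE])
  }
  stop("unrecognised transition specification")
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesize-or-load, accuracy assessment,
#' benefit-transfer valuation, fuzzy ecological-quality modelling for
#' both dates, and Markovian change analysis of both the land-cover
#' maps and the classified EQ maps. All outputs land in `outdir`
#' together with a JSON manifest carrying an MD5 checksum per file;
#' runs are deterministic given the seed, and every defaulted model
#' parameter is echoed to the log.
#'
#' @param config configuration list ([demoConfig()]) or path to a
#'   YAML/JSON file ([readRunConfig()]).
#' @param outdir output directory.
#' @param seed overrides `config$seed` when non-NULL.
#' @param verbose print log lines (default `TRUE`).
#' @return invisibly, a list with the in-memory results: rasters,
#'   accuracy metrics, valuation reports, EQ layers, transition
#'   matrices, flow tables and the manifest.
#' @export
runFull <- function(config = demoConfig(), outdir = tempfile("ecoscape_"),
                    seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateConfig(config)
  log <- function(...) if (verbose) message("[ecoscape] ", sprintf(...))
  seed <- as.integer(seed %||% config$seed %||% 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  covNames <- c("lst", "population", "carbon")
  if (!is.null(config$synthesis)) {
    syn <- config$synthesis
    log("synthesizing %d x %d landscape pair (seed %d)",
        syn$nrows, syn$ncols, seed)
    t0 <- stage("synth", generateLandscape(
      syn$nrows, syn$ncols, fractions = unlist(syn$fractions),
      smoothing = syn$smoothing %||% 5, seed = seed,
      cellsize = syn$cellsize %||% 10))
    P <- .asTransitionSpec(syn$transition %||% defaultTransitionSpec())
    t1 <- stage("synth", applyTransition(t0, P, seed = seed,
                                         mode = syn$mode %||% "random"))
    covspec <- syn$covariates %||% covariateDefaults()
    covs0 <- covs1 <- list()
    for (i in seq_along(covNames)) {
      nm <- covNames[i]
      sp <- covspec[[nm]]
      covs0[[nm]] <- generateCovariate(t0, unlist(sp$mean), unlist(sp$sd),
                                       seed = seed + 10L + i,
                                       units = sp$units %||% "")
      covs1[[nm]] <- generateCovariate(t1, unlist(sp$mean), unlist(sp$sd),
                                       seed = seed + 20L + i,
                                       units = sp$units %||% "")
    }
    refspec <- syn$reference %||% list(n = 600, error_rate = 0.05)
    points <- stage("accuracy", generateReferencePoints(
      t0, n = refspec$n, error_rate = refspec$error_rate, seed = seed))
  } else {
    inp <- config$inputs
    log("loading rasters from config inputs")
    t0 <- stage("read", readAsciiGrid(inp$t0, "categorical"))
    t1 <- stage("read", readAsciiGrid(inp$t1, "categorical"))
    covs0 <- covs1 <- list()
    for (nm in covNames) {
      covs0[[nm]] <- readAsciiGrid(inp$covariates[[nm]][[1L]], "continuous")
      covs1[[nm]] <- readAsciiGrid(inp$covariates[[nm]][[2L]], "continuous")
    }
    points <- NULL
    if (!is.null(inp$points))
      points <- utils::read.csv(inp$points)
  }
  stage("align", assertAligned(c(list(t0 = t0, t1 = t1), covs0, covs1)))

  accuracy <- NULL
  if (!is.null(points)) {
    accuracy <- stage("accuracy", assessAccuracy(points))
    log("accuracy: OA %.2f, kappa %.2f on %d points",
        accuracy$overall_accuracy, round(accuracy$kappa, 2), accuracy$n)
  }

  coeffs <- if (!is.null(config$coefficients))
    readCoefficientTable(config$coefficients) else esvCoefficients()
  esv <- stage("esv", runEsvTables(areaByClass(t0), areaByClass(t1),
                                   coeffs, outdir = outdir,
                                   labels = c("t0", "t1")))
  log("ESV totals: %.2f -> %.2f M US$/yr (round-then-sum)",
      esv$report0$total_rounded, esv$report1$total_rounded)

  membership <- config$membership %||% list()
  combine <- config$combine %||% list()
  log("EQ model: operator %s, gamma %.2f; function layers '%s', covariate layers '%s', spread %g",
      combine$operator %||% "gamma", combine$gamma %||% 0.9,
      membership$functions %||% "linear_small",
      membership$covariates %||% "large", membership$spread %||% 5)
  eq0 <- stage("eq", .eqForDate(t0, covs0, coeffs, membership, combine, log))
  eq1 <- stage("eq", .eqForDate(t1, covs1, coeffs, membership, combine, log))
  eqc0 <- classifyEQ(eq0); eqc1 <- classifyEQ(eq1)

  lulc_tm <- stage("change", transitionMatrix(t0, t1))
  eq_tm <- stage("change", transitionMatrix(eqc0, eqc1))
  flows <- stage("change", flowTable(eqc0, eqc1))
  nets <- stage("change", netChange(t0, t1))

  log("writing artifacts to %s", outdir)
  writeAsciiGrid(t0, file.path(outdir, "lulc_t0.asc"))
  writeAsciiGrid(t1, file.path(outdir, "lulc_t1.asc"))
  writeAsciiGrid(eq0, file.path(outdir, "eq_t0.asc"))
  writeAsciiGrid(eq1, file.path(outdir, "eq_t1.asc"))
  writeAsciiGrid(eqc0, file.path(outdir, "eq_class_t0.asc"))
  writeAsciiGrid(eqc1, file.path(outdir, "eq_class_t1.asc"))
  writeTransitionMatrix(lulc_tm, file.path(outdir, "lulc_transitions.csv"))
  writeTransitionMatrix(eq_tm, file.path(outdir, "eq_transitions.csv"))
  utils::write.csv(flows, file.path(outdir, "eq_flows.csv"),
                   row.names = FALSE)
  utils::write.csv(nets, file.path(outdir, "lulc_net_change.csv"),
                   row.names = FALSE)
  if (!is.null(points))
    utils::write.csv(points, file.path(outdir, "reference_points.csv"),
                     row.names = FALSE)
  if (!is.null(accuracy)) {
    utils::write.csv(as.data.frame(accuracy$confusion),
                     file.path(outdir, "confusion_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(metric = c("overall_accuracy", "kappa"),
                                value = c(accuracy$overall_accuracy,
                                          accuracy$kappa)),
                     file.path(outdir, "accuracy_metrics.csv"),
                     row.names = FALSE)
  }

  produced <- list.files(outdir, full.names = TRUE, recursive = TRUE)
  produced <- produced[!grepl("manifest\\.json$", produced)]
  manifest <- list(
    seed = seed,
    files = data.frame(path = basename(produced),
                       md5 = unname(tools::md5sum(produced)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(t0 = t0, t1 = t1, covariates = list(t0 = covs0, t1 = covs1),
                 points = points, accuracy = accuracy, esv = esv,
                 eq = list(t0 = eq0, t1 = eq1),
                 eq_class = list(t0 = eqc0, t1 = eqc1),
                 lulc_transitions = lulc_tm, eq_transitions = eq_tm,
                 eq_flows = flows, net_change = nets,
                 manifest = manifest, outdir = outdir))
}
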