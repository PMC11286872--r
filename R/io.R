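#' Write a response trace as a two-column CSV
#'
#' @param trace `data.frame(time_ms, value)`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("time_ms", "value") %in% names(trace)))
  .writeCsv(trace[, c("time_ms", "value")], path)
}

#' Write an electrode array as CSV (id, x_mm, y_mm, rad_mm, kind, s)
#'
#' @param array an [ElectrodeArray-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeArrayCsv <- function(array, path) {
  .writeCsv(arrayPositions(array), path)
}

#' CSV writer: UTF-8, comma, header, '.' decimal, 9 significant digits
#' @noRd
.writeCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Export a percept frame as a grayscale PNG
#'
#' Signed intensity is mapped with 0 at mid-gray so OFF-driven dark regions
#' are visible against the background, matching gray-background phosphene
#' renderings.
#'
#' @param frame numeric matrix (signed brightness) or a
#'   [PerceptMovie-class] (peak frame used)
#' @param path output file
#' @param maxAbs intensity mapped to full black/white (defaults to the
#'   frame's max |intensity|, or 1 for an all-zero frame)
#' @return `path`, invisibly
#' @export
writeFramePng <- function(frame, path, maxAbs = NULL) {
  if (is(frame, "PerceptMovie")) frame <- peakFrame(frame)$frame
  if (is.null(maxAbs)) maxAbs <- max(abs(frame), 1e-12)
  g <- pmin(pmax(0.5 + frame / (2 * maxAbs), 0), 1)
  # rows of the PNG run top-to-bottom; put +y up and x across
  png::writePNG(t(g)[rev(seq_len(ncol(g))), , drop = FALSE], path)
  invisible(path)
}

#' Export a percept movie as a numbered PNG stack
#'
#' @param movie a [PerceptMovie-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return vector of file paths, invisibly
#' @export
writeMoviePngStack <- function(movie, dir, prefix = "frame") {
  stopifnot(is(movie, "PerceptMovie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxAbs <- max(abs(movie@frames), 1e-12)
  paths <- vapply(seq_along(movie@timesMs), function(k) {
    p <- file.path(dir, sprintf("%s_%04d.png", prefix, k))
    writeFramePng(movie@frames[, , k], p, maxAbs = maxAbs)
    p
  }, character(1))
  invisible(paths)
}

#' Known configuration keys for [runSimulation()]
#' @noRd
.configKeys <- c("experiment", "seed", "outputDir",
                 "params", "map", "sheet", "electrode", "array", "train",
                 "eccs", "radEs", "ampFactors", "pwGrid", "fGrid",
                 "sequenceOnsetsMs", "nTarget", "eccRange", "rule")

#' @noRd
.requireKeys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
}

#' @noRd
.paramsFromConfig <- function(config) {
  p <- do.call(temporalParams, as.list(config$params %||% list()))
  calibrateThetaThresh(p)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.mapFromConfig <- function(config) {
  m <- config$map %||% list()
  if (is.character(m)) retinoPreset(m) else do.call(retinoMap, as.list(m))
}

#' Run an experiment family from a configuration
#'
#' The configuration (a list, or a path to a YAML/JSON file) selects one of
#' the experiment families — `phosphene-render`, `strength-duration`,
#' `size-vs-ecc`, `array-demo` or `letters-demo` — plus model parameters,
#' and names an output directory. CSV tables, PNG frames and a JSON
#' manifest (parameters, seed, package version) are written there; outputs
#' are deterministic given the config and seed. Unknown config keys are
#' rejected; missing required keys raise an error naming the key.
#'
#' @param config list or path to a YAML/JSON config file
#' @return list of result objects (also written to `outputDir`), invisibly
#' @export
runSimulation <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  .requireKeys(config, c("experiment", "outputDir"))
  exper <- config$experiment
  seed <- config$seed %||% 1
  outDir <- config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  params <- .paramsFromConfig(config)
  map <- .mapFromConfig(config)
  trainCfg <- config$train %||% list()
  train <- do.call(pulseTrain, utils::modifyList(
    list(amplitude = 60, pulseWidth = 0.25, frequency = 50,
         trainDuration = 0.5), as.list(trainCfg)))
  results <- list()

  if (exper == "phosphene-render") {
    .requireKeys(config, "electrode")
    el <- do.call(electrode, as.list(config$electrode))
    shCfg <- config$sheet %||% list()
    halfW <- shCfg$halfWidth %||% (el@rad + 1.6)
    sheet <- makeCorticalSheet(c(el@x - halfW, el@x + halfW),
                               c(el@y - halfW, el@y + halfW),
                               spacing = shCfg$spacing %||% 0.1,
                               map = map, seed = seed)
    movie <- renderPercept(sheet, el, train, params)
    ell <- quantifyEllipse(movie, thetaDraw = params@thetaDraw)
    .writeCsv(ell, file.path(outDir, "ellipse_stats.csv"))
    writeFramePng(movie, file.path(outDir, "percept_peak.png"))
    writeMoviePngStack(movie, file.path(outDir, "frames"))
    results <- list(movie = movie, ellipse = ell)
  } else if (exper == "strength-duration") {
    tab <- runStrengthDuration(params, pwGrid = config$pwGrid,
                               fGrid = config$fGrid)
    .writeCsv(tab, file.path(outDir, "strength_duration.csv"))
    results <- list(table = tab)
  } else if (exper == "size-vs-ecc") {
    tab <- runSizeExperiments(eccs = config$eccs %||% c(1, 3, 5, 10, 20),
                              radEs = config$radEs %||% 0.25,
                              ampFactors = config$ampFactors %||% 2,
                              params = params, seed = seed, map = map)
    .writeCsv(tab, file.path(outDir, "size_vs_ecc.csv"))
    results <- list(table = tab)
  } else if (exper == "array-demo") {
    arr <- generateArray(rule = config$rule %||% "optimal",
                         nTarget = config$nTarget %||% 24,
                         eccRange = config$eccRange %||% c(1, 20), map = map)
    writeArrayCsv(arr, file.path(outDir, "array.csv"))
    results <- list(array = arr)
  } else if (exper == "letters-demo") {
    arr <- gridArray(nrow = 4, ncol = 6, pitch = 2,
                     center = c(map@k * log(5 + map@a), 0), s = 1)
    pos <- arrayPositions(arr)
    sheet <- makeCorticalSheet(range(pos$x_mm) + c(-2, 2),
                               range(pos$y_mm) + c(-2, 2),
                               spacing = 0.15, map = map, seed = seed)
    idx <- config$electrode %||% c(1, 7, 13, 19)  # one column stroke
    onsets <- config$sequenceOnsetsMs %||% (100 * (seq_along(idx) - 1))
    letterTrain <- do.call(pulseTrain, utils::modifyList(
      list(amplitude = 1000, pulseWidth = 0.25, frequency = 200,
           trainDuration = 0.05), as.list(trainCfg)))
    sched <- lapply(seq_along(idx), function(k)
      list(electrode = arr@electrodes[[idx[k]]], train = letterTrain,
           onsetMs = onsets[k]))
    movie <- renderSequence(sheet, sched, params)
    writeMoviePngStack(movie, file.path(outDir, "frames"))
    writeArrayCsv(arr, file.path(outDir, "array.csv"))
    results <- list(movie = movie, array = arr)
  } else {
    stop("unknown experiment: ", exper)
  }

  manifest <- list(
    experiment = exper, seed = seed,
    package = as.character(utils::packageVersion("cortivis")),
    rVersion = R.version.string,
    config = config[setdiff(names(config), "outputDir")],
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Generate small deterministic fixtures
#'
#' A bundle of test assets: a 10 x 10 mm sheet at 0.1 mm spacing, a
#' 3-electrode array, reference pulse trains (including the 2 ms / 75 Hz /
#' 50 ms illustration train, which contains exactly 3 pulses), and a
#' synthetic noiseless threshold table generated at a known sensitivity
#' (s = 0.8) for recovery tests. Regenerates identically from the seed.
#'
#' @param seed RNG seed
#' @param params a [TemporalParams-class] (calibrated internally)
#' @return list with `sheet`, `array`, `trains`, `thresholdTable`,
#'   `trueS`, `seed`
#' @export
makeFixtures <- function(seed = 1, params = temporalParams()) {
  params <- calibrateThetaThresh(params)
  sheet <- makeCorticalSheet(c(18, 28), c(-5, 5), spacing = 0.1, seed = seed)
  arr <- electrodeArray(list(
    electrode("a", 20, 0, 0.25),
    electrode("b", 23, 1, 0.25),
    electrode("c", 26, -1, 1)), layout = list(rule = "fixture"))
  trains <- list(
    fig1 = pulseTrain(60, pulseWidth = 2, frequency = 75,
                      trainDuration = 0.05),
    standard = standardTrain())
  trueS <- 0.8
  conds <- expand.grid(pw_ms = c(0.1, 0.2, 0.4, 0.8), freq_hz = c(50, 100))
  thr <- vapply(seq_len(nrow(conds)), function(i) {
    tmpl <- pulseTrain(1, conds$pw_ms[i], conds$freq_hz[i], 0.5)
    findThreshold(tmpl, params, s = trueS, tol = 1e-6)$threshold_uA
  }, numeric(1))
  tab <- data.frame(electrode = "fix1", conds, dur_s = 0.5,
                    threshold_uA = thr)
  list(sheet = sheet, array = arr, trains = trains, thresholdTable = tab,
       trueS = trueS, seed = seed)
}
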