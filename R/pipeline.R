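# The end-to-end workflow: simulate -> detect -> quantify -> classify,
# bound together by a validated run configuration, per-stage child seeds and
# provenance-stamped outputs.

#' Default run configuration
#'
#' Nested-list configuration of a full pipeline run (the schema
#' [readRunConfig()] validates against). Populations may name the built-in
#' presets (`"A549"`, `"CAL27"`) or spell out the moments.
#'
#' @param nCellsPerType Cells simulated per population (default 500).
#' @param seed Global seed; per-stage seeds derive from it via
#'   [childSeed()].
#' @param trainLstm Whether the LSTM stage runs (it dominates run time).
#' @return A named list (class `flowLadderConfig`).
#' @export
defaultRunConfig <- function(nCellsPerType = 500, seed = 1L,
                             trainLstm = TRUE) {
  structure(list(
    seed = seed,
    nCellsPerType = nCellsPerType,
    chunkSize = 250,
    populations = c("A549", "CAL27"),
    channel = list(noiseSdMv = 1.5, spillover = "identity"),
    detection = list(medianWindow = 50, thresholdK = 3,
                     minEventSamples = 250, coincidenceToleranceMs = 1),
    geometry = list(windowLengthUm = 60, crossSectionUm2 = 400),
    calibration = list(dilutions = calibrationDilutions(),
                       stocks = as.list(defaultStockConcentrations()),
                       noiseless = TRUE),
    train = list(fractions = c(0.70, 0.15, 0.15), hiddenUnitsFfnn = 50,
                 lstmHidden = 128, batchSize = 100, learningRate = 0.001,
                 maxEpochs = 50, patience = 5, seqLength = 256,
                 lstm = trainLstm)
  ), class = "flowLadderConfig")
}

# Recursively reject keys absent from the reference schema.
checkKeys <- function(x, ref, path = "") {
  if (!is.list(x) || !is.list(ref) || is.null(names(ref))) return(invisible())
  extra <- setdiff(names(x), names(ref))
  if (length(extra)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  }
  for (nm in intersect(names(x), names(ref))) {
    checkKeys(x[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
}

#' Read and validate a run configuration
#'
#' Loads YAML or JSON, overlays it on [defaultRunConfig()], and rejects
#' unknown keys.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list (class `flowLadderConfig`).
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ref <- defaultRunConfig()
  checkKeys(raw, ref)
  merged <- modifyList(ref, raw)
  class(merged) <- "flowLadderConfig"
  merged
}

configPopulations <- function(config) {
  lapply(config$populations, function(p) {
    if (is.character(p)) {
      switch(p, A549 = a549Params(), CAL27 = cal27Params(),
             stop(sprintf("unknown population preset '%s'", p)))
    } else {
      PopulationParams(p$name, p$copiesMean, p$copiesSd, p$diameterMean,
                       p$diameterSd, p$velocityMean, p$velocitySd,
                       if (is.null(p$arrivalRate)) 100 else p$arrivalRate)
    }
  })
}

configChannel <- function(config) {
  sp <- config$channel$spillover
  spill <- if (is.character(sp)) {
    switch(sp, identity = diag(3), preset = spilloverPreset(),
           stop(sprintf("unknown spillover preset '%s'", sp)))
  } else {
    matrix(unlist(sp), 3, 3)
  }
  defaultChannelConfig(spillover = spill,
                       noiseSdMv = config$channel$noiseSdMv)
}

configDetection <- function(config) {
  do.call(DetectionSettings, config$detection)
}

configTrain <- function(config, seed) {
  tr <- config$train
  TrainConfig(fractions = tr$fractions,
              hiddenUnitsFfnn = tr$hiddenUnitsFfnn,
              lstmHidden = tr$lstmHidden, batchSize = tr$batchSize,
              learningRate = tr$learningRate, maxEpochs = tr$maxEpochs,
              patience = tr$patience, seqLength = tr$seqLength, seed = seed)
}

#' Render, detect and ladder-fit a cell table in chunks
#'
#' Memory-bounded driver of the render -> filter -> detect -> fit -> match
#' chain: cells are rendered `chunkSize` at a time (each chunk a separate
#' seeded trace), processed with [processTrace()], and the matched fits
#' concatenated on the global time axis. Optionally collects fixed-length
#' pulse sequences for the LSTM while each chunk's trace is in memory.
#'
#' @param cells Ground-truth cell `data.frame`.
#' @param cfg A [ChannelConfig-class].
#' @param settings A [DetectionSettings-class].
#' @param seed Stage seed (per-chunk seeds derive from it).
#' @param chunkSize Cells per rendered chunk.
#' @param collectPulses If TRUE, also return an `(n, seqLength, 3)` array
#'   of resampled pulses.
#' @param seqLength Resampled pulse length.
#' @return List: `matched` (global matched fit table), `counts`
#'   (summed per-chunk counters), `sequences` (array or NULL).
#' @export
detectAndFitCells <- function(cells, cfg, settings = defaultDetectionSettings(),
                              seed = 1L, chunkSize = 250,
                              collectPulses = FALSE, seqLength = 256) {
  nCells <- nrow(cells)
  chunks <- if (nCells == 0) list() else
    split(seq_len(nCells), ceiling(seq_len(nCells) / chunkSize))
  matchedList <- list()
  seqList <- list()
  counts <- list(detected = c(0L, 0L, 0L), matched = 0L,
                 dropped = c(0L, 0L, 0L), doubletFlagged = 0L,
                 doubletExcluded = 0L)
  for (ci in seq_along(chunks)) {
    sub <- cells[chunks[[ci]], , drop = FALSE]
    offset <- sub$arrivalTimeS[1] - 5e-3
    sub$arrivalTimeS <- sub$arrivalTimeS - offset
    trace <- renderTrace(sub, cfg, seed = childSeed(seed, 100 + ci))
    res <- processTrace(trace, settings)
    m <- res$matched
    if (collectPulses && nrow(m) > 0) {
      seqList[[length(seqList) + 1L]] <-
        extractPulses(res$filtered, m, L = seqLength)
    }
    if (nrow(m) > 0) {
      m$tCenterS <- m$tCenterS + offset
      matchedList[[length(matchedList) + 1L]] <- m
    }
    counts$detected <- counts$detected + res$counts$detected
    counts$matched <- counts$matched + res$counts$matched
    counts$dropped <- counts$dropped + res$counts$dropped
    counts$doubletFlagged <- counts$doubletFlagged + res$counts$doubletFlagged
    counts$doubletExcluded <- counts$doubletExcluded +
      res$counts$doubletExcluded
  }
  matched <- if (length(matchedList)) do.call(rbind, matchedList)
             else emptyMatched()
  rownames(matched) <- NULL
  sequences <- if (collectPulses && length(seqList)) {
    do.call(abind3, seqList)
  } else NULL
  list(matched = matched, counts = counts, sequences = sequences)
}

# rbind for (n, L, C) arrays along the first dimension.
abind3 <- function(...) {
  parts <- list(...)
  L <- dim(parts[[1]])[2]; C <- dim(parts[[1]])[3]
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, L, C))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Build the three per-channel calibration curves
#'
#' Renders a gradient dilution series per channel with the configured stock
#' concentrations and fits the lines.
#'
#' @param cfg A [ChannelConfig-class] (noise set as desired; acceptance-type
#'   analyses use a noiseless series).
#' @param stocks Named molar stock concentrations (mol/L) per channel.
#' @param dilutions Dilution factors.
#' @param seed Stage seed.
#' @return List of three [CalibrationCurve-class] objects (FITC, PE, PerCP).
#' @export
buildCalibrationCurves <- function(cfg, stocks = defaultStockConcentrations(),
                                   dilutions = calibrationDilutions(),
                                   seed = 1L) {
  lapply(seq_along(CHANNELS), function(c) {
    series <- renderCalibrationSeries(dilutions, stocks[[CHANNELS[c]]], cfg,
                                      seed = childSeed(seed, 200 + c),
                                      channel = CHANNELS[c])
    calibrateFromTraces(series, channel = CHANNELS[c])
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> detect -> quantify -> classify for every configured
#' population and writes all artifacts (ground truth, events, calibration
#' curves, cell records, classifier reports) under `outDir`, each stamped
#' with the configuration hash and seed. Identical configuration and seed
#' give identical outputs.
#'
#' @param config A configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outDir Output directory (created if needed).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "detect", "quantify", "classify")` (later stages need
#'   the earlier ones in the same call).
#' @return Invisible list with the key artifacts (`cells`, `records`,
#'   `curves`, `reports`, `counts`, `paths`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile(),
                        stages = c("simulate", "detect", "quantify",
                                   "classify")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(unclass(config))
  seed <- config$seed
  pops <- configPopulations(config)
  cfg <- configChannel(config)
  settings <- configDetection(config)
  geometry <- GeometryModel(config$geometry$windowLengthUm,
                            config$geometry$crossSectionUm2)
  out <- list(paths = character(0), counts = list())

  message(sprintf("[simulate] %d populations x %d cells (seed %d, config %s)",
                  length(pops), config$nCellsPerType, seed, hash))
  cells <- lapply(seq_along(pops), function(k) {
    samplePopulation(pops[[k]], config$nCellsPerType,
                     seed = childSeed(seed, k),
                     windowLengthUm = cfg@windowLengthUm)
  })
  names(cells) <- vapply(pops, function(p) p@name, "")
  for (nm in names(cells)) {
    p <- file.path(outDir, sprintf("ground_truth_%s.csv", nm))
    writeTableWithProvenance(cells[[nm]], p, seed, hash)
    out$paths <- c(out$paths, p)
  }
  out$cells <- cells
  if (!"detect" %in% stages) return(invisible(out))

  calCfg <- if (isTRUE(config$calibration$noiseless)) {
    ChannelConfig(cfg@gain, cfg@baselineMv, 0, cfg@sampleRateHz,
                  cfg@windowLengthUm, cfg@crossSectionUm2, cfg@spillover,
                  cfg@asymmetry)
  } else cfg
  curves <- buildCalibrationCurves(calCfg,
                                   stocks = unlist(config$calibration$stocks),
                                   dilutions = config$calibration$dilutions,
                                   seed = seed)
  for (c in seq_along(curves)) {
    p <- file.path(outDir, sprintf("calibration_%s.json", CHANNELS[c]))
    writeCalibrationCurve(curves[[c]], p, seed, hash)
    out$paths <- c(out$paths, p)
  }
  out$curves <- curves

  wantLstm <- isTRUE(config$train$lstm) && "classify" %in% stages
  detected <- lapply(seq_along(cells), function(k) {
    message(sprintf("[detect] population %s", names(cells)[k]))
    detectAndFitCells(cells[[k]], cfg, settings,
                      seed = childSeed(seed, 300 + k),
                      chunkSize = config$chunkSize,
                      collectPulses = wantLstm,
                      seqLength = config$train$seqLength)
  })
  names(detected) <- names(cells)
  events <- do.call(rbind, lapply(names(detected), function(nm) {
    m <- detected[[nm]]$matched
    if (nrow(m)) cbind(population = nm, m) else NULL
  }))
  if (is.null(events)) events <- cbind(population = character(0),
                                       emptyMatched())
  p <- file.path(outDir, "events.csv")
  writeTableWithProvenance(events, p, seed, hash)
  out$paths <- c(out$paths, p)
  out$counts <- lapply(detected, `[[`, "counts")
  message(sprintf("[detect] matched %s cells",
                  paste(vapply(detected, function(d) d$counts$matched, 0L),
                        collapse = " + ")))
  if (!"quantify" %in% stages) return(invisible(out))

  records <- do.call(rbind, lapply(names(detected), function(nm) {
    r <- quantifyCells(detected[[nm]]$matched, curves, geometry,
                       spillover = cfg@spillover)
    if (nrow(r)) cbind(population = nm, r) else NULL
  }))
  p <- file.path(outDir, "cell_records.csv")
  writeTableWithProvenance(records, p, seed, hash)
  out$paths <- c(out$paths, p)
  out$records <- records
  message(sprintf("[quantify] %d records (%d clipped, %d flagged)",
                  nrow(records), sum(records$clipped), sum(records$flagged)))
  if (!"classify" %in% stages || length(cells) < 2) return(invisible(out))

  trainCfg <- configTrain(config, seed = childSeed(seed, 400))
  labels <- factor(records$population, levels = names(cells))
  reports <- list()
  reports$ffnn <- trainFFNN(
    records[, c("copiesFitc", "copiesPe", "copiesPercp")], labels, trainCfg)
  if (wantLstm) {
    sequences <- do.call(abind3, lapply(detected, `[[`, "sequences"))
    reports$lstm <- trainLSTM(sequences, labels, trainCfg)
  }
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    jsonlite::write_json(
      c(list(model = nm, accuracy = as.list(rep@accuracy),
             confusion = rep@confusion, flags = rep@flags),
        provenance(seed, hash)),
      file.path(outDir, sprintf("report_%s.json", nm)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeTableWithProvenance(rep@trace,
      file.path(outDir, sprintf("accuracy_trace_%s.csv", nm)), seed, hash)
    out$paths <- c(out$paths,
                   file.path(outDir, sprintf("report_%s.json", nm)),
                   file.path(outDir, sprintf("accuracy_trace_%s.csv", nm)))
    message(sprintf("[classify] %s test accuracy %.3f", nm,
                    reportAccuracy(rep, "test")))
  }
  out$reports <- reports
  invisible(out)
}
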