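#' Population parameters of a cell type
#'
#' Generative description of one cell type: per-channel protein copy-number
#' moments, cell diameter and traveling velocity moments, and the arrival
#' rate in the microchannel. All positive quantities are drawn from
#' moment-matched lognormal distributions (see [lognormalMoments()]), so the
#' configured means and SDs are exactly the population moments.
#'
#' @slot name Cell-type label.
#' @slot copiesMean,copiesSd Numeric length-3, mean/SD of protein copies per
#'   cell for the FITC (beta-actin), PE (EpCAM) and PerCP (beta-tubulin)
#'   channels.
#' @slot diameterMean,diameterSd Cell diameter moments, micrometres.
#' @slot velocityMean,velocitySd Transit velocity moments, micrometres per
#'   millisecond.
#' @slot arrivalRate Mean cell arrival rate, events per second.
#'
#' @seealso [a549Params()], [cal27Params()], [samplePopulation()]
#' @export
setClass("PopulationParams",
  representation(
    name = "character",
    copiesMean = "numeric", copiesSd = "numeric",
    diameterMean = "numeric", diameterSd = "numeric",
    velocityMean = "numeric", velocitySd = "numeric",
    arrivalRate = "numeric"
  )
)

setValidity("PopulationParams", function(object) {
  errs <- character()
  if (length(object@name) != 1) errs <- c(errs, "'name' must be length 1")
  for (s in c("copiesMean", "copiesSd")) {
    v <- slot(object, s)
    if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0)) {
      errs <- c(errs, sprintf("'%s' must be 3 positive numbers", s))
    }
  }
  for (s in c("diameterMean", "diameterSd", "velocityMean", "velocitySd",
              "arrivalRate")) {
    e <- checkPositive(slot(object, s), s)
    if (!is.null(e)) errs <- c(errs, e)
  }
  if (length(errs)) errs else TRUE
})

#' Construct population parameters
#'
#' @param name Cell-type label.
#' @param copiesMean,copiesSd Length-3 copy-number moments (FITC, PE, PerCP).
#' @param diameterMean,diameterSd Diameter moments, um.
#' @param velocityMean,velocitySd Velocity moments, um/ms.
#' @param arrivalRate Cells per second entering the channel.
#' @return A [PopulationParams-class] object.
#' @export
PopulationParams <- function(name, copiesMean, copiesSd,
                             diameterMean, diameterSd,
                             velocityMean, velocitySd,
                             arrivalRate = 100) {
  new("PopulationParams",
    name = name,
    copiesMean = as.numeric(copiesMean), copiesSd = as.numeric(copiesSd),
    diameterMean = diameterMean, diameterSd = diameterSd,
    velocityMean = velocityMean, velocitySd = velocitySd,
    arrivalRate = arrivalRate
  )
}

setMethod("show", "PopulationParams", function(object) {
  cat(sprintf("PopulationParams '%s'\n", object@name))
  cat(sprintf("  copies/cell  : %s (mean), %s (sd)  [%s]\n",
    paste(signif(object@copiesMean, 3), collapse = ", "),
    paste(signif(object@copiesSd, 3), collapse = ", "),
    paste(CHANNELS, collapse = "/")))
  cat(sprintf("  diameter     : %.2f +/- %.2f um\n",
    object@diameterMean, object@diameterSd))
  cat(sprintf("  velocity     : %.2f +/- %.2f um/ms\n",
    object@velocityMean, object@velocitySd))
  cat(sprintf("  arrival rate : %.1f cells/s\n", object@arrivalRate))
})

#' Detector and channel-geometry configuration
#'
#' Forward intensity map of the instrument emulation: per-channel gain
#' (mV per molecule in the detection volume), baseline, additive Gaussian
#' noise, sampling rate, the illuminated window length along the flow axis
#' and the channel cross-section, and the spectral spillover matrix.
#'
#' @slot gain Numeric length-3, mV per molecule for FITC/PE/PerCP.
#' @slot baselineMv Baseline voltage, mV.
#' @slot noiseSdMv Gaussian noise SD per raw sample, mV.
#' @slot sampleRateHz Sampling rate, Hz (instrument default 500 kHz).
#' @slot windowLengthUm Illuminated window length along flow, micrometres.
#' @slot crossSectionUm2 Channel cross-section, square micrometres
#'   (20 um x 20 um constriction by default).
#' @slot spillover 3x3 unit-diagonal mixing matrix applied to the per-channel
#'   trapezoid amplitudes (identity = no spectral crosstalk).
#' @slot asymmetry Fall/rise time ratio of rendered pulses; 1 for the
#'   constant-velocity symmetric trapezoid.
#' @seealso [defaultChannelConfig()], [renderTrace()]
#' @export
setClass("ChannelConfig",
  representation(
    gain = "numeric", baselineMv = "numeric", noiseSdMv = "numeric",
    sampleRateHz = "numeric", windowLengthUm = "numeric",
    crossSectionUm2 = "numeric", spillover = "matrix", asymmetry = "numeric"
  )
)

setValidity("ChannelConfig", function(object) {
  errs <- character()
  if (length(object@gain) != 3 || any(object@gain <= 0)) {
    errs <- c(errs, "'gain' must be 3 positive numbers")
  }
  if (!is.numeric(object@noiseSdMv) || object@noiseSdMv < 0) {
    errs <- c(errs, "'noiseSdMv' must be >= 0")
  }
  for (s in c("sampleRateHz", "windowLengthUm", "crossSectionUm2",
              "asymmetry")) {
    e <- checkPositive(slot(object, s), s)
    if (!is.null(e)) errs <- c(errs, e)
  }
  sp <- object@spillover
  if (!all(dim(sp) == c(3, 3))) {
    errs <- c(errs, "'spillover' must be a 3x3 matrix")
  } else {
    if (any(abs(diag(sp) - 1) > 1e-12)) {
      errs <- c(errs, "'spillover' diagonal entries must equal 1")
    }
    if (abs(det(sp)) < 1e-12) errs <- c(errs, "'spillover' must be invertible")
  }
  if (length(errs)) errs else TRUE
})

#' Construct a detector configuration
#'
#' @param gain mV per molecule, length 3 (FITC, PE, PerCP).
#' @param baselineMv Baseline level, mV.
#' @param noiseSdMv Additive Gaussian noise SD, mV.
#' @param sampleRateHz Sampling rate, Hz.
#' @param windowLengthUm Detection window length along flow, um.
#' @param crossSectionUm2 Channel cross-section, um^2.
#' @param spillover 3x3 unit-diagonal mixing matrix.
#' @param asymmetry Fall-time / rise-time ratio of rendered pulses.
#' @return A [ChannelConfig-class] object.
#' @export
ChannelConfig <- function(gain, baselineMv = 5, noiseSdMv = 1.5,
                          sampleRateHz = 5e5, windowLengthUm = 60,
                          crossSectionUm2 = 400, spillover = diag(3),
                          asymmetry = 1) {
  new("ChannelConfig",
    gain = as.numeric(gain), baselineMv = baselineMv, noiseSdMv = noiseSdMv,
    sampleRateHz = sampleRateHz, windowLengthUm = windowLengthUm,
    crossSectionUm2 = crossSectionUm2, spillover = spillover,
    asymmetry = asymmetry
  )
}

setMethod("show", "ChannelConfig", function(object) {
  cat("ChannelConfig\n")
  cat(sprintf("  gain (mV/molecule): %s\n",
    paste(signif(object@gain, 4), collapse = ", ")))
  cat(sprintf("  baseline %.2f mV, noise sd %.2f mV, %.0f kHz\n",
    object@baselineMv, object@noiseSdMv, object@sampleRateHz / 1e3))
  cat(sprintf("  window %.1f um, cross-section %.0f um^2\n",
    object@windowLengthUm, object@crossSectionUm2))
  offdiag <- object@spillover[row(object@spillover) != col(object@spillover)]
  cat(sprintf("  spillover: %s\n",
    if (all(offdiag == 0)) "identity" else "non-identity (compensation needed)"))
})

#' Multi-channel detector trace
#'
#' A uniformly sampled three-channel voltage recording in millivolts, the
#' raw material of pulse processing. Stored as an n x 3 numeric matrix with
#' channel names as column names.
#'
#' @slot values Numeric matrix, samples x channels, mV.
#' @slot sampleRateHz Sampling rate, Hz.
#' @seealso [renderTrace()], [medianFilterTrace()], [detectEvents()]
#' @export
setClass("RawTrace",
  representation(values = "matrix", sampleRateHz = "numeric")
)

setValidity("RawTrace", function(object) {
  errs <- character()
  if (!is.numeric(object@values)) errs <- c(errs, "'values' must be numeric")
  if (is.null(colnames(object@values))) {
    errs <- c(errs, "'values' must have channel names as colnames")
  }
  e <- checkPositive(object@sampleRateHz, "sampleRateHz")
  if (!is.null(e)) errs <- c(errs, e)
  if (length(errs)) errs else TRUE
})

#' Construct a trace
#' @param values Numeric matrix (samples x channels), mV.
#' @param sampleRateHz Sampling rate in Hz.
#' @param channelNames Channel names; defaults to FITC/PE/PerCP for 3 columns.
#' @return A [RawTrace-class] object.
#' @export
RawTrace <- function(values, sampleRateHz = 5e5, channelNames = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- if (!is.null(channelNames)) channelNames
      else if (ncol(values) == 3) CHANNELS
      else paste0("ch", seq_len(ncol(values)))
  }
  new("RawTrace", values = values, sampleRateHz = sampleRateHz)
}

#' Number of samples per channel
#' @param trace A [RawTrace-class].
#' @return Integer sample count.
#' @export
nSamples <- function(trace) nrow(trace@values)

setMethod("show", "RawTrace", function(object) {
  n <- nrow(object@values)
  cat(sprintf("RawTrace: %d samples x %d channels (%s) @ %.0f kHz, %.3f s\n",
    n, ncol(object@values), paste(colnames(object@values), collapse = ", "),
    object@sampleRateHz / 1e3, n / object@sampleRateHz))
  cat(sprintf("  range: [%.2f, %.2f] mV\n",
    min(object@values), max(object@values)))
})

#' Trace values accessor
#' @param trace A [RawTrace-class].
#' @return The samples x channels matrix (mV).
#' @export
traceValues <- function(trace) trace@values

#' Sampling rate accessor
#' @param trace A [RawTrace-class].
#' @return Sampling rate in Hz.
#' @export
sampleRate <- function(trace) trace@sampleRateHz

#' Detection-volume geometry of the constrictional microchannel
#'
#' The constriction forces single-file transit through a fixed illuminated
#' volume: window length along the flow axis times the channel cross-section.
#' This volume is what makes the solution-based calibration equivalent to a
#' transiting cell's signal.
#'
#' @slot windowLengthUm Window length along flow, micrometres.
#' @slot crossSectionUm2 Cross-section, square micrometres.
#' @seealso [detectionVolumeL()], [moleculesInVolume()]
#' @export
setClass("GeometryModel",
  representation(windowLengthUm = "numeric", crossSectionUm2 = "numeric")
)

setValidity("GeometryModel", function(object) {
  errs <- c(checkPositive(object@windowLengthUm, "windowLengthUm"),
            checkPositive(object@crossSectionUm2, "crossSectionUm2"))
  if (length(errs)) errs else TRUE
})

#' Construct a geometry model
#' @param windowLengthUm Detection window length, um (default 60).
#' @param crossSectionUm2 Channel cross-section, um^2 (default 20 x 20).
#' @return A [GeometryModel-class] object.
#' @export
GeometryModel <- function(windowLengthUm = 60, crossSectionUm2 = 400) {
  new("GeometryModel", windowLengthUm = windowLengthUm,
      crossSectionUm2 = crossSectionUm2)
}

#' Detection volume in litres
#'
#' `window_length x cross_section`, converted from cubic micrometres
#' (1 um^3 = 1e-15 L).
#'
#' @param geometry A [GeometryModel-class].
#' @return Volume in litres.
#' @examples
#' detectionVolumeL(GeometryModel(60, 400)) # 2.4e-11 L
#' @export
detectionVolumeL <- function(geometry) {
  geometry@windowLengthUm * geometry@crossSectionUm2 * 1e-15
}

setMethod("show", "GeometryModel", function(object) {
  cat(sprintf(
    "GeometryModel: window %.1f um x cross-section %.0f um^2 = %.3g L\n",
    object@windowLengthUm, object@crossSectionUm2, detectionVolumeL(object)))
})

#' Pulse-detection settings
#'
#' @slot medianWindow Median-filter window, samples (odd; default 50 is
#'   rounded up to 51 internally).
#' @slot thresholdK Threshold multiplier k in `mean + k * sd`.
#' @slot minEventSamples Minimum suprathreshold run length, samples.
#' @slot coincidenceToleranceMs Max per-pair timestamp offset when matching
#'   events across channels, ms.
#' @seealso [detectEvents()], [matchChannels()]
#' @export
setClass("DetectionSettings",
  representation(
    medianWindow = "numeric", thresholdK = "numeric",
    minEventSamples = "numeric", coincidenceToleranceMs = "numeric"
  )
)

setValidity("DetectionSettings", function(object) {
  errs <- character()
  if (object@medianWindow < 1) errs <- c(errs, "'medianWindow' must be >= 1")
  if (object@thresholdK <= 0) errs <- c(errs, "'thresholdK' must be > 0")
  if (object@minEventSamples < 1) {
    errs <- c(errs, "'minEventSamples' must be >= 1")
  }
  if (object@coincidenceToleranceMs <= 0) {
    errs <- c(errs, "'coincidenceToleranceMs' must be > 0")
  }
  if (length(errs)) errs else TRUE
})

#' Construct detection settings
#' @param medianWindow Median filter window in samples.
#' @param thresholdK Multiplier k of the `mean + k * sd` event threshold.
#' @param minEventSamples Minimum event length in samples.
#' @param coincidenceToleranceMs Cross-channel matching tolerance, ms.
#' @return A [DetectionSettings-class] object.
#' @export
DetectionSettings <- function(medianWindow = 50, thresholdK = 3,
                              minEventSamples = 250,
                              coincidenceToleranceMs = 1) {
  new("DetectionSettings", medianWindow = medianWindow,
      thresholdK = thresholdK, minEventSamples = minEventSamples,
      coincidenceToleranceMs = coincidenceToleranceMs)
}

setMethod("show", "DetectionSettings", function(object) {
  cat(sprintf(paste0(
    "DetectionSettings: median window %d, threshold mean + %g sd, ",
    "min length %d samples, coincidence %.2f ms\n"),
    as.integer(object@medianWindow), object@thresholdK,
    as.integer(object@minEventSamples), object@coincidenceToleranceMs))
})

#' Per-channel calibration curve
#'
#' Ordinary least-squares line relating the number of fluorophore-conjugated
#' molecules in the detection volume to the measured plateau intensity above
#' baseline: `I = slope * N + intercept`.
#'
#' @slot channel Channel name.
#' @slot slope mV per molecule (must be > 0).
#' @slot intercept mV.
#' @slot rSquared Coefficient of determination of the fit.
#' @slot points data.frame with columns `nMolecules`, `intensityMv`.
#' @seealso [fitCalibrationCurve()], [intensityToCopies()]
#' @export
setClass("CalibrationCurve",
  representation(
    channel = "character", slope = "numeric", intercept = "numeric",
    rSquared = "numeric", points = "data.frame"
  )
)

setValidity("CalibrationCurve", function(object) {
  errs <- character()
  if (object@slope <= 0) errs <- c(errs, "'slope' must be > 0")
  if (nrow(object@points) < 2) errs <- c(errs, "need >= 2 calibration points")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12) {
    errs <- c(errs, "'rSquared' must be in [0, 1]")
  }
  if (length(errs)) errs else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s]: I = %.4g mV/molecule x N + %.3g mV (R^2 = %.6f, %d points)\n",
    object@channel, object@slope, object@intercept, object@rSquared,
    nrow(object@points)))
})

#' Training configuration for the classifiers
#'
#' @slot fractions Train/validation/test split fractions (sum to 1).
#' @slot hiddenUnitsFfnn Hidden-layer width of the feedforward net.
#' @slot lstmHidden LSTM hidden-state width.
#' @slot batchSize Mini-batch size.
#' @slot learningRate Optimizer learning rate.
#' @slot maxEpochs Epoch cap.
#' @slot patience Early-stopping patience (epochs without validation
#'   improvement).
#' @slot seqLength Fixed resampled pulse length fed to the LSTM.
#' @slot seed RNG seed for splitting and weight initialization.
#' @seealso [trainFFNN()], [trainLSTM()]
#' @export
setClass("TrainConfig",
  representation(
    fractions = "numeric", hiddenUnitsFfnn = "numeric",
    lstmHidden = "numeric", batchSize = "numeric", learningRate = "numeric",
    maxEpochs = "numeric", patience = "numeric", seqLength = "numeric",
    seed = "numeric"
  )
)

setValidity("TrainConfig", function(object) {
  errs <- character()
  if (length(object@fractions) != 3 ||
      abs(sum(object@fractions) - 1) > 1e-9 || any(object@fractions <= 0)) {
    errs <- c(errs, "'fractions' must be 3 positive numbers summing to 1")
  }
  for (s in c("hiddenUnitsFfnn", "lstmHidden", "batchSize", "learningRate",
              "maxEpochs", "seqLength")) {
    e <- checkPositive(slot(object, s), s)
    if (!is.null(e)) errs <- c(errs, e)
  }
  if (length(errs)) errs else TRUE
})

#' Construct a training configuration
#' @param fractions Split fractions, default `c(0.70, 0.15, 0.15)`.
#' @param hiddenUnitsFfnn Feedforward hidden units (default 50).
#' @param lstmHidden LSTM hidden units (default 128).
#' @param batchSize Mini-batch size (default 100).
#' @param learningRate Learning rate (default 0.001).
#' @param maxEpochs Epoch cap (default 50).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seqLength Resampled pulse length for the LSTM (default 256).
#' @param seed RNG seed.
#' @return A [TrainConfig-class] object.
#' @export
TrainConfig <- function(fractions = c(0.70, 0.15, 0.15),
                        hiddenUnitsFfnn = 50, lstmHidden = 128,
                        batchSize = 100, learningRate = 0.001,
                        maxEpochs = 50, patience = 5, seqLength = 256,
                        seed = 1L) {
  new("TrainConfig", fractions = fractions,
      hiddenUnitsFfnn = hiddenUnitsFfnn, lstmHidden = lstmHidden,
      batchSize = batchSize, learningRate = learningRate,
      maxEpochs = maxEpochs, patience = patience, seqLength = seqLength,
      seed = seed)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0(
    "TrainConfig: split %s | FFNN %d hidden | LSTM %d hidden, batch %d, ",
    "lr %g, <= %d epochs (patience %d), L = %d, seed %d\n"),
    paste(object@fractions, collapse = "/"),
    as.integer(object@hiddenUnitsFfnn), as.integer(object@lstmHidden),
    as.integer(object@batchSize), object@learningRate,
    as.integer(object@maxEpochs), as.integer(object@patience),
    as.integer(object@seqLength), as.integer(object@seed)))
})

#' Classifier evaluation report
#'
#' @slot model Model label ("ffnn" or "lstm").
#' @slot accuracy Named numeric: train, validation, test, overall accuracy.
#' @slot confusion 2x2 test-set confusion matrix, rows = truth,
#'   columns = prediction, fixed class order.
#' @slot trace data.frame of per-epoch train/validation accuracy.
#' @slot config The [TrainConfig-class] used.
#' @slot flags Character vector of condition flags (e.g. non-convergence).
#' @export
setClass("ClassifierReport",
  representation(
    model = "character", accuracy = "numeric", confusion = "matrix",
    trace = "data.frame", config = "TrainConfig", flags = "character"
  )
)

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport [%s]\n", object@model))
  cat(sprintf(
    "  accuracy: train %.3f | validation %.3f | test %.3f | overall %.3f\n",
    object@accuracy[["train"]], object@accuracy[["validation"]],
    object@accuracy[["test"]], object@accuracy[["overall"]]))
  cat("  test confusion matrix (rows = truth):\n")
  print(object@confusion)
  if (length(object@flags)) {
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  }
})

#' Accuracy accessor
#' @param report A [ClassifierReport-class].
#' @param which One of "train", "validation", "test", "overall".
#' @return Accuracy in `[0, 1]`.
#' @export
reportAccuracy <- function(report, which = "test") {
  report@accuracy[[which]]
}

#' Confusion-matrix accessor
#' @param report A [ClassifierReport-class].
#' @return The 2x2 test confusion matrix.
#' @export
reportConfusion <- function(report) report@confusion
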