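# Published population moments for the two demonstration cell lines and the
# matching instrument defaults. Copy numbers are per cell; channel order is
# FITC (beta-actin), PE (EpCAM), PerCP (beta-tubulin).

#' A549-like population parameters
#'
#' Lung-carcinoma (A549) population moments: beta-actin 1.78e6 +/- 1.06e6,
#' EpCAM 5.6e3 +/- 4.3e3, beta-tubulin 8.11e4 +/- 4.89e4 copies per cell;
#' diameter 15.2 +/- 4.0 um; velocity 16.32 +/- 13.12 um/ms.
#'
#' @param arrivalRate Cells per second (default 100).
#' @return A [PopulationParams-class] object.
#' @export
a549Params <- function(arrivalRate = 100) {
  PopulationParams("A549",
    copiesMean = c(1.78e6, 0.56e4, 8.11e4),
    copiesSd = c(1.06e6, 0.43e4, 4.89e4),
    diameterMean = 15.2, diameterSd = 4.0,
    velocityMean = 16.32, velocitySd = 13.12,
    arrivalRate = arrivalRate
  )
}

#' CAL 27-like population parameters
#'
#' Tongue squamous-carcinoma (CAL 27) population moments: beta-actin
#' 2.65e6 +/- 1.19e6, EpCAM 3.47e4 +/- 2.45e4, beta-tubulin
#' 8.61e4 +/- 5.25e4 copies per cell; diameter 16.6 +/- 4.0 um; velocity
#' 17.16 +/- 5.35 um/ms.
#'
#' @param arrivalRate Cells per second (default 100).
#' @return A [PopulationParams-class] object.
#' @export
cal27Params <- function(arrivalRate = 100) {
  PopulationParams("CAL27",
    copiesMean = c(2.65e6, 3.47e4, 8.61e4),
    copiesSd = c(1.19e6, 2.45e4, 5.25e4),
    diameterMean = 16.6, diameterSd = 4.0,
    velocityMean = 17.16, velocitySd = 5.35,
    arrivalRate = arrivalRate
  )
}

#' Default detector configuration
#'
#' Gains are anchored so the A549 copy-number means map onto the typical
#' plateau voltages of each channel (about 29.7 / 80.5 / 25.4 mV): the
#' absolute mV-per-molecule scale of a PMT is arbitrary, but using the same
#' forward map for cells and calibration solutions makes copy-number
#' recovery exact by construction. Baseline 5 mV, noise SD 1.5 mV,
#' 500 kHz sampling, 60 um window over a 20 x 20 um constriction.
#'
#' @param spillover 3x3 unit-diagonal mixing matrix (default identity).
#' @param noiseSdMv Additive noise SD, mV.
#' @return A [ChannelConfig-class] object.
#' @export
defaultChannelConfig <- function(spillover = diag(3), noiseSdMv = 1.5) {
  ChannelConfig(
    gain = c(29.7 / 1.78e6, 80.5 / 0.56e4, 25.4 / 8.11e4),
    baselineMv = 5, noiseSdMv = noiseSdMv, sampleRateHz = 5e5,
    windowLengthUm = 60, crossSectionUm2 = 400, spillover = spillover
  )
}

#' Default detection-volume geometry
#' @return A [GeometryModel-class]: 60 um window x 400 um^2 cross-section
#'   (2.4e-11 L).
#' @export
defaultGeometry <- function() GeometryModel(60, 400)

#' Default pulse-detection settings
#' @return A [DetectionSettings-class]: 50-point median filter,
#'   mean + 3 sd threshold, 250-sample (0.5 ms) minimum event, 1 ms
#'   coincidence tolerance.
#' @export
defaultDetectionSettings <- function() DetectionSettings()

#' Non-identity spillover preset
#'
#' A plausible emission-crosstalk matrix for FITC/PE/PerCP detection bands,
#' provided to exercise spectral compensation; values are synthetic.
#'
#' @return A 3x3 unit-diagonal invertible matrix.
#' @export
spilloverPreset <- function() {
  matrix(c(
    1.00, 0.12, 0.01,
    0.08, 1.00, 0.05,
    0.00, 0.04, 1.00
  ), nrow = 3, byrow = TRUE, dimnames = list(CHANNELS, CHANNELS))
}

#' Default antibody stock concentrations for calibration runs
#'
#' Chosen so a 1:100 dilution of each stock places roughly the typical
#' cell-plateau voltage of that channel in the detection volume; values are
#' package defaults, not measured quantities.
#'
#' @return Named numeric vector of molar stock concentrations (mol/L).
#' @export
defaultStockConcentrations <- function() {
  c(FITC = 12e-6, PE = 40e-9, PerCP = 560e-9)
}

# Canonical dilution series of the gradient calibration runs.
#' Gradient dilution factors used for calibration
#' @return Numeric vector `c(10, 50, 100, 500, 1000, 5000)`.
#' @export
calibrationDilutions <- function() c(10, 50, 100, 500, 1000, 5000)
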