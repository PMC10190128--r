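# Volume-equivalence quantification: calibration curves from gradient
# dilution runs, plateau intensity -> absolute copy number, spectral
# compensation, and kinematic inversion of pulse timing.

#' Expected molecule count in the detection volume
#'
#' `N = concentration x detection_volume x N_Avogadro`. This is the
#' volume-equivalence principle: a solution of known molar concentration
#' filling the illuminated constriction presents a computable number of
#' fluorophores, so its plateau voltage anchors the molecule scale.
#'
#' @param concentration Molar concentration, mol/L (>= 0).
#' @param geometry A [GeometryModel-class].
#' @return Expected molecule count (not rounded).
#' @examples
#' moleculesInVolume(1e-9, GeometryModel(60, 400)) # ~1.445e4
#' @export
moleculesInVolume <- function(concentration, geometry) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  concentration * detectionVolumeL(geometry) * AVOGADRO
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of plateau intensity on molecule count,
#' `I = slope x N + intercept`. Refuses degenerate inputs and non-positive
#' slopes (an unusable detector response).
#'
#' @param points `data.frame` with columns `nMolecules` and `intensityMv`
#'   (>= 2 distinct `nMolecules` values).
#' @param channel Channel label stored on the curve.
#' @return A [CalibrationCurve-class].
#' @export
fitCalibrationCurve <- function(points, channel = "FITC") {
  if (!all(c("nMolecules", "intensityMv") %in% names(points))) {
    stop("calibration error: need columns nMolecules, intensityMv")
  }
  if (nrow(points) < 2 || length(unique(points$nMolecules)) < 2) {
    stop("calibration error: need >= 2 distinct molecule counts")
  }
  fit <- lm(intensityMv ~ nMolecules, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration error: non-positive slope")
  }
  ssTot <- sum((points$intensityMv - mean(points$intensityMv))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  new("CalibrationCurve", channel = channel, slope = slope,
      intercept = unname(coef(fit)[1]), rSquared = min(max(r2, 0), 1),
      points = points[, c("nMolecules", "intensityMv")])
}

#' Build a calibration curve from rendered dilution runs
#'
#' Measures each run's plateau level above its own quiet margins on the
#' run's channel, pairs it with the computed molecule count, and fits the
#' line with [fitCalibrationCurve()].
#'
#' @param series Output of [renderCalibrationSeries()].
#' @param channel Channel name or index the series was acquired on.
#' @return A [CalibrationCurve-class].
#' @export
calibrateFromTraces <- function(series, channel = "FITC") {
  chan <- if (is.character(channel)) match(channel, CHANNELS) else as.integer(channel)
  pts <- do.call(rbind, lapply(series, function(run) {
    x <- traceValues(run$trace)[, chan]
    data.frame(
      nMolecules = run$nMolecules,
      intensityMv = mean(x[run$plateauIdx]) - mean(x[run$marginIdx])
    )
  }))
  fitCalibrationCurve(pts, channel = CHANNELS[chan])
}

#' Apply spectral spillover compensation
#'
#' Inverts the linear channel mixing: returns `spillover^{-1} %*% I`.
#' Identity spillover leaves intensities unchanged.
#'
#' @param intensities Numeric length-3 vector or n x 3 matrix of plateau
#'   intensities, mV.
#' @param spillover 3x3 invertible mixing matrix.
#' @return Compensated intensities, same shape as the input.
#' @export
applyCompensation <- function(intensities, spillover) {
  if (!all(dim(spillover) == c(3, 3))) stop("spillover must be 3x3")
  if (abs(det(spillover)) < 1e-12) {
    stop("compensation error: singular spillover matrix")
  }
  if (is.matrix(intensities)) {
    t(solve(spillover, t(intensities)))
  } else {
    as.numeric(solve(spillover, intensities))
  }
}

#' Convert a plateau intensity to a molecule count
#'
#' `copies = (I_f - intercept) / slope`, the inverse of the calibration
#' line; negative results are clipped to zero and flagged so event counts
#' stay stable.
#'
#' @param intensityMv Plateau intensity above baseline, mV.
#' @param curve A [CalibrationCurve-class].
#' @param equivalenceFactor Multiplicative cell-vs-solution geometry
#'   correction (default 1).
#' @return Numeric vector of copy numbers with attribute `clipped`
#'   (logical vector marking clipped entries).
#' @export
intensityToCopies <- function(intensityMv, curve, equivalenceFactor = 1) {
  validObject(curve)
  copies <- equivalenceFactor * (intensityMv - curve@intercept) / curve@slope
  clipped <- copies < 0
  copies[clipped] <- 0
  attr(copies, "clipped") <- clipped
  copies
}

#' Invert ladder timing into velocity, diameter and transit time
#'
#' For a cell of diameter d crossing a window of length L at constant
#' velocity v, the trapezoid has rise `T_a = d/v`, plateau
#' `T_s = (L - d)/v` and fall `T_d = T_a`, so with
#' `T_rise = (T_a + T_d)/2`: `v = L / (T_rise + T_s)` and
#' `d = v x T_rise`; `transit = T_a + T_s + T_d`. This closed-form
#' inversion of the trapezoid geometry is the package's diameter model.
#'
#' @param taMs,tsMs,tdMs Fitted rise/plateau/fall durations, ms (vectors).
#' @param geometry A [GeometryModel-class].
#' @return `data.frame` with `velocityUmPerMs`, `diameterUm`, `transitMs`,
#'   `flagged` (TRUE where the total duration is zero and no inversion
#'   exists).
#' @examples
#' kinematicsFromPulse(1, 2, 1, GeometryModel(60, 400)) # v = 20, d = 20
#' @export
kinematicsFromPulse <- function(taMs, tsMs, tdMs, geometry) {
  tRise <- (taMs + tdMs) / 2
  total <- tRise + tsMs
  flagged <- !is.finite(total) | total <= 0
  v <- ifelse(flagged, NA_real_, geometry@windowLengthUm / total)
  d <- ifelse(flagged, NA_real_, v * tRise)
  data.frame(velocityUmPerMs = v, diameterUm = d,
             transitMs = taMs + tsMs + tdMs, flagged = flagged)
}

#' Quantify matched events into per-cell records
#'
#' The full quantification stage: spectral compensation of the fitted
#' plateau triple, conversion to absolute copy numbers through the
#' per-channel calibration curves, and kinematic inversion of the pulse
#' timing. Timing is taken from the channel with the largest fitted plateau
#' (best signal-to-noise) of each cell.
#'
#' @param matched Matched fit table from [processTrace()].
#' @param curves List of three [CalibrationCurve-class] objects
#'   (FITC, PE, PerCP).
#' @param geometry A [GeometryModel-class].
#' @param spillover 3x3 spillover matrix used during acquisition
#'   (default identity).
#' @param equivalenceFactor Cell-vs-solution volume-equivalence correction
#'   (default 1).
#' @return A `data.frame` of cell records: `cellId`, `tCenterS`,
#'   `copiesFitc`, `copiesPe`, `copiesPercp`, `velocityUmPerMs`,
#'   `diameterUm`, `transitMs`, `ifMv1..3`, `clipped`, `flagged`.
#' @export
quantifyCells <- function(matched, curves, geometry = defaultGeometry(),
                          spillover = diag(3), equivalenceFactor = 1) {
  stopifnot(length(curves) == 3)
  n <- nrow(matched)
  if (n == 0) {
    return(data.frame(cellId = integer(0), tCenterS = numeric(0),
                      copiesFitc = numeric(0), copiesPe = numeric(0),
                      copiesPercp = numeric(0), velocityUmPerMs = numeric(0),
                      diameterUm = numeric(0), transitMs = numeric(0),
                      clipped = logical(0), flagged = logical(0)))
  }
  intens <- as.matrix(matched[, c("ifMv1", "ifMv2", "ifMv3")])
  comp <- applyCompensation(intens, spillover)
  copies <- matrix(0, n, 3)
  clippedAny <- rep(FALSE, n)
  for (c in 1:3) {
    cp <- intensityToCopies(comp[, c], curves[[c]], equivalenceFactor)
    copies[, c] <- as.numeric(cp)
    clippedAny <- clippedAny | attr(cp, "clipped")
  }
  # timing from the best-SNR (largest plateau) channel of each cell
  best <- max.col(comp, ties.method = "first")
  pick <- function(stub) {
    vapply(seq_len(n), function(i) matched[[paste0(stub, best[i])]][i], 0)
  }
  kin <- kinematicsFromPulse(pick("taMs"), pick("tsMs"), pick("tdMs"),
                             geometry)
  data.frame(
    cellId = seq_len(n), tCenterS = matched$tCenterS,
    copiesFitc = copies[, 1], copiesPe = copies[, 2],
    copiesPercp = copies[, 3],
    velocityUmPerMs = kin$velocityUmPerMs, diameterUm = kin$diameterUm,
    transitMs = kin$transitMs,
    ifMv1 = comp[, 1], ifMv2 = comp[, 2], ifMv3 = comp[, 3],
    clipped = clippedAny, flagged = kin$flagged
  )
}
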