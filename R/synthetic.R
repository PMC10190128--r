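# Synthetic instrument emulation: ground-truth cells and rendered
# three-channel PMT traces with the trapezoidal ("ladder") pulse model the
# analysis assumes. Everything is seeded so downstream stages have exact,
# download-free test inputs.

#' Construct a ground-truth cell table
#'
#' Plain-data representation of latent cells behind a rendered trace. Used
#' directly when a prescribed transit-time or plateau distribution is needed
#' instead of [samplePopulation()] draws.
#'
#' @param arrivalTimeS Arrival time of each cell at the window entrance, s.
#' @param copies Matrix (n x 3) or length-3 vector of molecule counts per
#'   channel (FITC, PE, PerCP); rounded to non-negative integers.
#' @param diameterUm Cell diameters, um.
#' @param velocityUmPerMs Transit velocities, um/ms.
#' @return A `data.frame` with columns `cellId`, `arrivalTimeS`,
#'   `copiesFitc`, `copiesPe`, `copiesPercp`, `diameterUm`,
#'   `velocityUmPerMs`.
#' @export
groundTruthCells <- function(arrivalTimeS, copies, diameterUm,
                             velocityUmPerMs) {
  n <- length(arrivalTimeS)
  copies <- matrix(as.numeric(copies), nrow = n, ncol = 3)
  copies <- pmax(round(copies), 0)
  if (any(diameterUm <= 0) || any(velocityUmPerMs <= 0)) {
    stop("diameters and velocities must be positive")
  }
  data.frame(
    cellId = seq_len(n),
    arrivalTimeS = as.numeric(arrivalTimeS),
    copiesFitc = copies[, 1], copiesPe = copies[, 2], copiesPercp = copies[, 3],
    diameterUm = as.numeric(diameterUm),
    velocityUmPerMs = as.numeric(velocityUmPerMs)
  )
}

# Total transit duration (entry of leading edge to exit of trailing edge)
# in ms: (window + diameter) / velocity.
cellTransitMs <- function(cells, windowLengthUm) {
  (windowLengthUm + cells$diameterUm) / cells$velocityUmPerMs
}

#' Draw ground-truth cells from a population
#'
#' Copy numbers, diameter and velocity are drawn from moment-matched
#' lognormal distributions (positive support, exact first two moments);
#' arrival times follow a homogeneous Poisson process at `arrivalRate`
#' with arrivals pushed apart so that consecutive pulses are separated by at
#' least `spacingFactor` times the mean of their own transit durations
#' (a non-overlap guarantee).
#'
#' @param params A [PopulationParams-class].
#' @param nCells Number of cells (>= 0).
#' @param seed RNG seed.
#' @param windowLengthUm Detection-window length used for the transit-time
#'   spacing rule, um.
#' @param spacingFactor Minimum spacing in units of the mean pairwise
#'   transit duration (default 3).
#' @param startMarginS Quiet time before the first arrival, s.
#' @return A ground-truth cell `data.frame` (see [groundTruthCells()]).
#' @examples
#' cells <- samplePopulation(a549Params(), 5, seed = 1)
#' cells$diameterUm
#' @export
samplePopulation <- function(params, nCells, seed = 1L,
                             windowLengthUm = 60, spacingFactor = 3,
                             startMarginS = 5e-3) {
  validObject(params)
  stopifnot(nCells >= 0)
  if (nCells == 0) {
    return(groundTruthCells(numeric(0), matrix(numeric(0), 0, 3),
                            numeric(0), numeric(0)))
  }
  set.seed(seed)
  copies <- sapply(1:3, function(c) {
    rlnormMoments(nCells, params@copiesMean[c], params@copiesSd[c])
  })
  copies <- matrix(copies, nrow = nCells)
  diameter <- rlnormMoments(nCells, params@diameterMean, params@diameterSd)
  velocity <- rlnormMoments(nCells, params@velocityMean, params@velocitySd)

  gaps <- rexp(nCells, rate = params@arrivalRate)
  transitS <- (windowLengthUm + diameter) / velocity / 1e3
  arrival <- numeric(nCells)
  arrival[1] <- startMarginS + gaps[1]
  if (nCells > 1) {
    for (i in 2:nCells) {
      minGap <- spacingFactor * (transitS[i - 1] + transitS[i]) / 2
      arrival[i] <- arrival[i - 1] + max(gaps[i], minGap)
    }
  }
  groundTruthCells(arrival, copies, diameter, velocity)
}

# Unit trapezoid profile at times t (seconds): rise over [t0, t0+ta],
# plateau over [t0+ta, t0+ta+ts], fall over the next td. Zero-duration
# ramps degenerate to steps.
trapezoidProfile <- function(t, t0, ta, ts, td) {
  rise <- if (ta > 0) (t - t0) / ta else as.numeric(t >= t0)
  tEnd <- t0 + ta + ts + td
  fall <- if (td > 0) (tEnd - t) / td else as.numeric(t <= tEnd)
  p <- pmin.int(rise, fall)
  p[p > 1] <- 1
  p[p < 0] <- 0
  p
}

#' Render a three-channel detector trace
#'
#' Forward model of a cell transit: on channel c the pulse is a trapezoid of
#' amplitude `gain[c] * copies[c]` (then mixed by the spillover matrix) with
#' rise time `T_a = diameter / velocity`, plateau
#' `T_s = (window - diameter) / velocity` and fall `T_d = asymmetry * T_a`,
#' added to the baseline; i.i.d. Gaussian noise is added per raw sample.
#' Identical `(cells, cfg, seed)` give bit-identical traces.
#'
#' @param cells Ground-truth cell `data.frame` (possibly empty).
#' @param cfg A [ChannelConfig-class].
#' @param seed RNG seed for the noise.
#' @param paddingS Quiet padding appended after the last pulse, s.
#' @param durationS Optional total duration override, s (must cover all
#'   pulses).
#' @return A [RawTrace-class].
#' @examples
#' cells <- samplePopulation(a549Params(), 3, seed = 7)
#' tr <- renderTrace(cells, defaultChannelConfig(), seed = 7)
#' @export
renderTrace <- function(cells, cfg, seed = 1L, paddingS = 5e-3,
                        durationS = NULL) {
  validObject(cfg)
  fs <- cfg@sampleRateHz
  if (nrow(cells) > 0 && any(cells$diameterUm >= cfg@windowLengthUm)) {
    stop("geometry error: cell diameter must be smaller than the window length")
  }
  transitS <- if (nrow(cells)) cellTransitMs(cells, cfg@windowLengthUm) / 1e3
              else numeric(0)
  endS <- if (nrow(cells)) max(cells$arrivalTimeS + transitS) else 0
  totalS <- if (is.null(durationS)) endS + paddingS else durationS
  if (totalS < endS) stop("durationS does not cover all pulses")
  n <- max(ceiling(totalS * fs), 1)

  set.seed(seed)
  values <- matrix(cfg@baselineMv, nrow = n, ncol = 3)
  if (cfg@noiseSdMv > 0) {
    values <- values + rnorm(3L * n, sd = cfg@noiseSdMv)
  }
  colnames(values) <- CHANNELS

  if (nrow(cells) > 0) {
    amps <- cfg@spillover %*%
      (cfg@gain * t(as.matrix(cells[, c("copiesFitc", "copiesPe",
                                        "copiesPercp")])))
    for (i in seq_len(nrow(cells))) {
      d <- cells$diameterUm[i]
      v <- cells$velocityUmPerMs[i]
      ta <- d / v / 1e3
      ts <- (cfg@windowLengthUm - d) / v / 1e3
      td <- cfg@asymmetry * ta
      t0 <- cells$arrivalTimeS[i]
      i0 <- max(floor(t0 * fs), 0) + 1L
      i1 <- min(ceiling((t0 + ta + ts + td) * fs) + 1L, n)
      if (i1 < i0) next
      tt <- (seq.int(i0, i1) - 1) / fs
      prof <- trapezoidProfile(tt, t0, ta, ts, td)
      values[i0:i1, ] <- values[i0:i1, ] + outer(prof, amps[, i])
    }
  }
  RawTrace(values, sampleRateHz = fs)
}

#' Render a gradient-dilution calibration series
#'
#' Emulates flushing dilutions of a fluorophore-conjugated antibody stock
#' through the constriction: each run is a constant plateau at
#' `gain x N(dilution)` above baseline (mixed by spillover) between quiet
#' margins, where `N(dilution) = moleculesInVolume(stock / dilution)` for
#' the detection volume implied by `cfg`.
#'
#' @param dilutions Positive dilution factors (e.g. `calibrationDilutions()`).
#' @param stockConcentration Stock molar concentration, mol/L.
#' @param cfg A [ChannelConfig-class].
#' @param seed RNG seed.
#' @param channel Channel (name or index) whose antibody is being diluted.
#' @param plateauS Plateau duration per run, s.
#' @param marginS Quiet margin before and after the plateau, s.
#' @return A list with one element per dilution:
#'   `list(dilution, nMolecules, trace, plateauIdx, marginIdx)` where the
#'   index vectors delimit the plateau and the quiet margins (run metadata a
#'   real acquisition would log as solution-switch times).
#' @export
renderCalibrationSeries <- function(dilutions, stockConcentration, cfg,
                                    seed = 1L, channel = "FITC",
                                    plateauS = 2e-2, marginS = 5e-3) {
  validObject(cfg)
  if (any(dilutions <= 0) || stockConcentration <= 0) {
    stop("dilutions and stock concentration must be positive")
  }
  chan <- if (is.character(channel)) match(channel, CHANNELS) else as.integer(channel)
  if (is.na(chan) || chan < 1 || chan > 3) stop("unknown channel")
  geometry <- GeometryModel(cfg@windowLengthUm, cfg@crossSectionUm2)
  fs <- cfg@sampleRateHz
  nMargin <- round(marginS * fs)
  nPlateau <- round(plateauS * fs)
  n <- 2L * nMargin + nPlateau

  lapply(seq_along(dilutions), function(k) {
    nMol <- moleculesInVolume(stockConcentration / dilutions[k], geometry)
    level <- numeric(3)
    level[chan] <- cfg@gain[chan] * nMol
    level <- as.numeric(cfg@spillover %*% level)
    set.seed(childSeed(seed, k))
    values <- matrix(cfg@baselineMv, nrow = n, ncol = 3)
    plateauIdx <- seq.int(nMargin + 1L, nMargin + nPlateau)
    values[plateauIdx, ] <- values[plateauIdx, ] + rep(level, each = nPlateau)
    if (cfg@noiseSdMv > 0) values <- values + rnorm(3L * n, sd = cfg@noiseSdMv)
    colnames(values) <- CHANNELS
    list(
      dilution = dilutions[k], nMolecules = nMol,
      trace = RawTrace(values, sampleRateHz = fs),
      plateauIdx = plateauIdx,
      marginIdx = c(seq_len(nMargin), seq.int(nMargin + nPlateau + 1L, n))
    )
  })
}
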