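# Pulse processing: median filtering, robust background statistics,
# mean + k*sd event detection, ladder (trapezoid) fitting and cross-channel
# coincidence matching. All sample intervals are 0-based and half-open.

#' Median-filter a trace
#'
#' Sliding-window median per channel with replicate padding at the edges, the
#' standard PMT background-noise suppression step before event detection.
#' Even window lengths are rounded up to the next odd length.
#'
#' @param trace A [RawTrace-class].
#' @param window Window length in samples (default 50).
#' @return A [RawTrace-class] of identical length; output values are bounded
#'   by the input range.
#' @export
medianFilterTrace <- function(trace, window = 50) {
  x <- traceValues(trace)
  n <- nrow(x)
  if (n == 0) stop("trace is empty")
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window longer than trace")
  k <- as.integer(window)
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(trace)
  h <- (k - 1L) %/% 2L
  out <- apply(x, 2, function(col) {
    padded <- c(rep(col[1], h), col, rep(col[n], h))
    runmed(padded, k, endrule = "keep")[(h + 1L):(h + n)]
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  RawTrace(out, sampleRateHz = sampleRate(trace))
}

#' Estimate per-channel background statistics and detection threshold
#'
#' Two-pass estimate designed to stay calibrated when a large fraction of the
#' recording is pulse: pass one forms a provisional threshold from the
#' median and MAD (robust to suprathreshold mass), pass two computes the
#' mean and SD over the sub-provisional samples only; the event threshold is
#' `mean + thresholdK * sd`. A zero-variance channel gets
#' `threshold = mean` and a `zero-variance` flag.
#'
#' @param trace A (median-filtered) [RawTrace-class].
#' @param thresholdK Threshold multiplier (default 3).
#' @return A `data.frame` with one row per channel: `channel`, `meanMv`,
#'   `sdMv`, `thresholdMv`, `flag`.
#' @export
estimateBackground <- function(trace, thresholdK = 3) {
  x <- traceValues(trace)
  res <- lapply(seq_len(ncol(x)), function(c) {
    col <- x[, c]
    provisional <- median(col) + thresholdK * mad(col)
    sub <- col[col <= provisional]
    if (length(sub) < 2) sub <- col
    m <- mean(sub)
    s <- sd(sub)
    flag <- ""
    if (!is.finite(s) || s == 0) {
      s <- 0
      flag <- "zero-variance"
    }
    data.frame(channel = colnames(x)[c], meanMv = m, sdMv = s,
               thresholdMv = m + thresholdK * s, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Maximal suprathreshold runs of a single channel; returns (start, end)
# 1-based inclusive indices.
suprathresholdRuns <- function(col, threshold) {
  above <- col > threshold
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect pulse events on each channel
#'
#' Maximal contiguous suprathreshold runs at least `minEventSamples` long
#' become events; each event's boundaries are then extended outward to the
#' nearest crossing of the background mean, so the full trapezoid support
#' (not just its suprathreshold core) is captured for fitting.
#'
#' @param trace A median-filtered [RawTrace-class].
#' @param settings A [DetectionSettings-class].
#' @param background Output of [estimateBackground()]; computed from `trace`
#'   if missing.
#' @return A `data.frame` ordered by channel then start, with columns
#'   `channel`, `startIndex`, `endIndex` (0-based, half-open over samples),
#'   `peakMv`.
#' @export
detectEvents <- function(trace, settings = defaultDetectionSettings(),
                         background = NULL) {
  validObject(settings)
  if (is.null(background)) {
    background <- estimateBackground(trace, settings@thresholdK)
  }
  x <- traceValues(trace)
  n <- nrow(x)
  out <- lapply(seq_len(ncol(x)), function(c) {
    col <- x[, c]
    bg <- background[c, ]
    runs <- suprathresholdRuns(col, bg$thresholdMv)
    if (nrow(runs) == 0) {
      return(data.frame(channel = character(0), startIndex = integer(0),
                        endIndex = integer(0), peakMv = numeric(0)))
    }
    runs <- runs[runs$end - runs$start + 1L >= settings@minEventSamples, ,
                 drop = FALSE]
    if (nrow(runs) == 0) {
      return(data.frame(channel = character(0), startIndex = integer(0),
                        endIndex = integer(0), peakMv = numeric(0)))
    }
    # extend to the nearest baseline (background-mean) crossing
    below <- col <= bg$meanMv
    prevEnd <- 0L
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]
      while (s > prevEnd + 1L && !below[s - 1L]) s <- s - 1L
      e <- runs$end[i]
      nextStart <- if (i < nrow(runs)) runs$start[i + 1L] else n + 1L
      while (e < nextStart - 1L && e < n && !below[e + 1L]) e <- e + 1L
      runs$start[i] <- s
      runs$end[i] <- e
      prevEnd <- e
    }
    peak <- vapply(seq_len(nrow(runs)),
                   function(i) max(col[runs$start[i]:runs$end[i]]), 0)
    data.frame(channel = colnames(x)[c],
               startIndex = runs$start - 1L,   # 0-based
               endIndex = runs$end,            # half-open
               peakMv = peak, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit a ladder (trapezoid) shape to one pulse segment
#'
#' Least-squares fit of a trapezoid with four free breakpoints and one
#' plateau level to a baseline-subtracted segment: initial breakpoints come
#' from the 10\%/90\% level crossings, then a Nelder-Mead refinement
#' minimizes the squared error. Breakpoints are continuous-time, so timing
#' resolution is not limited to the sample grid. Long segments are decimated
#' for the fit (every m-th sample, m chosen to keep about 3000 points).
#'
#' @param segment Numeric vector, the filtered samples spanning the pulse
#'   (including some baseline on both sides).
#' @param sampleRateHz Sampling rate, Hz.
#' @param baselineMv Background mean to subtract, mV.
#' @param tStartS Trace time of the first segment sample, s.
#' @return A one-row `data.frame`: `taMs`, `tsMs`, `tdMs` (rise, plateau,
#'   fall durations), `ifMv` (plateau above baseline), `fitResidual`
#'   (RMS mV), `tCenterS`, `converged`.
#' @export
fitLadder <- function(segment, sampleRateHz, baselineMv = 0, tStartS = 0) {
  y <- as.numeric(segment) - baselineMv
  n <- length(y)
  if (n < 4 || max(y) <= 0) {
    return(data.frame(taMs = NA_real_, tsMs = NA_real_, tdMs = NA_real_,
                      ifMv = NA_real_, fitResidual = NA_real_,
                      tCenterS = NA_real_, converged = FALSE))
  }
  m <- max(1L, ceiling(n / 800))
  idx <- seq.int(1L, n, by = m)
  tt <- (idx - 1) / sampleRateHz
  yy <- y[idx]
  syy <- sum(yy^2)

  peak <- max(yy)
  a0 <- median(yy[yy >= 0.9 * peak])
  crossUp <- function(level) tt[which(yy >= level)[1]]
  crossDown <- function(level) tt[max(which(yy >= level))]
  t10r <- crossUp(0.1 * a0); t90r <- crossUp(0.9 * a0)
  t90f <- crossDown(0.9 * a0); t10f <- crossDown(0.1 * a0)
  ta0 <- max((t90r - t10r) / 0.8, 1 / sampleRateHz)
  td0 <- max((t10f - t90f) / 0.8, 1 / sampleRateHz)
  t00 <- t10r - 0.125 * ta0
  ts0 <- max((t90f - 0.1 * td0) - (t90r + 0.1 * ta0), 0)

  # plateau level is profiled out in closed form (linear in the model),
  # leaving a 4-dimensional breakpoint search
  ampFor <- function(p) {
    prof <- trapezoidProfile(tt, p[1], max(p[2], 0), max(p[3], 0),
                             max(p[4], 0))
    spp <- sum(prof^2)
    if (spp == 0) return(list(amp = 0, sse = syy))
    syp <- sum(yy * prof)
    list(amp = syp / spp, sse = syy - syp^2 / spp)
  }
  fit <- optim(c(t00, ta0, ts0, td0), function(p) ampFor(p)$sse,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-11))
  p <- fit$par
  ta <- max(p[2], 0); ts <- max(p[3], 0); td <- max(p[4], 0)
  data.frame(
    taMs = ta * 1e3, tsMs = ts * 1e3, tdMs = td * 1e3,
    ifMv = ampFor(p)$amp,
    fitResidual = sqrt(max(fit$value, 0) / length(yy)),
    tCenterS = tStartS + p[1] + (ta + ts + td) / 2,
    converged = fit$convergence == 0
  )
}

# Fit every detected event of one trace; returns per-channel fit tables with
# event metadata. fitMarginFrac of the event length (at least 100 samples)
# of extra baseline is included on each side of the fitted segment.
fitEvents <- function(trace, events, background, fitMarginFrac = 0.3) {
  x <- traceValues(trace)
  fs <- sampleRate(trace)
  n <- nrow(x)
  if (nrow(events) == 0) {
    return(cbind(events,
                 data.frame(taMs = numeric(0), tsMs = numeric(0),
                            tdMs = numeric(0), ifMv = numeric(0),
                            fitResidual = numeric(0), tCenterS = numeric(0),
                            converged = logical(0))))
  }
  chIdx <- match(events$channel, colnames(x))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    s <- events$startIndex[i] + 1L          # back to 1-based inclusive
    e <- events$endIndex[i]
    margin <- max(100L, ceiling(fitMarginFrac * (e - s + 1L)))
    s2 <- max(1L, s - margin)
    e2 <- min(n, e + margin)
    f <- fitLadder(x[s2:e2, chIdx[i]], fs,
                   baselineMv = background$meanMv[chIdx[i]],
                   tStartS = (s2 - 1) / fs)
    cbind(events[i, , drop = FALSE], f, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Match events across the three channels into per-cell triples
#'
#' Greedy nearest-time matching: walking the first channel's events in time
#' order, each is paired with the nearest unused event of every other
#' channel; a triple is kept when all pairwise center-time offsets are
#' within `toleranceMs`. Unmatched events are dropped and counted.
#'
#' @param fitsPerChannel List of three fit `data.frame`s (one per channel,
#'   as produced by [processTrace()] internals), each with a `tCenterS`
#'   column, sorted by time.
#' @param toleranceMs Maximum pairwise center-time offset, ms.
#' @return A `data.frame` with one row per matched cell: `tCenterS` plus the
#'   per-channel fitted parameters suffixed 1..3 (`taMs1`, `ifMv1`, ...).
#'   Attribute `dropped` holds the per-channel unmatched counts.
#' @export
matchChannels <- function(fitsPerChannel, toleranceMs = 1) {
  stopifnot(length(fitsPerChannel) == 3)
  tolS <- toleranceMs / 1e3
  f1 <- fitsPerChannel[[1]]; f2 <- fitsPerChannel[[2]]; f3 <- fitsPerChannel[[3]]
  used2 <- rep(FALSE, nrow(f2)); used3 <- rep(FALSE, nrow(f3))
  keep <- list()
  for (i in seq_len(nrow(f1))) {
    t1 <- f1$tCenterS[i]
    if (!is.finite(t1)) next
    j <- nearestUnused(t1, f2$tCenterS, used2)
    k <- nearestUnused(t1, f3$tCenterS, used3)
    if (is.na(j) || is.na(k)) next
    t2 <- f2$tCenterS[j]; t3 <- f3$tCenterS[k]
    if (max(abs(c(t1 - t2, t1 - t3, t2 - t3))) > tolS) next
    used2[j] <- TRUE; used3[k] <- TRUE
    keep[[length(keep) + 1L]] <- cbind(
      tCenterS = mean(c(t1, t2, t3)),
      renameFit(f1[i, , drop = FALSE], 1),
      renameFit(f2[j, , drop = FALSE], 2),
      renameFit(f3[k, , drop = FALSE], 3)
    )
  }
  matched <- if (length(keep)) do.call(rbind, keep) else emptyMatched()
  rownames(matched) <- NULL
  nMatched <- nrow(matched)
  attr(matched, "dropped") <- c(
    nrow(f1) - nMatched, nrow(f2) - nMatched, nrow(f3) - nMatched)
  matched
}

nearestUnused <- function(t, times, used) {
  ok <- which(!used & is.finite(times))
  if (!length(ok)) return(NA_integer_)
  ok[which.min(abs(times[ok] - t))]
}

fitCarryCols <- c("taMs", "tsMs", "tdMs", "ifMv", "fitResidual",
                  "startIndex", "endIndex")

renameFit <- function(row, suffix) {
  out <- row[, fitCarryCols, drop = FALSE]
  names(out) <- paste0(fitCarryCols, suffix)
  out
}

emptyMatched <- function() {
  cols <- c("tCenterS", paste0(rep(fitCarryCols, 3),
                               rep(1:3, each = length(fitCarryCols))))
  as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Run the full pulse-processing stage on a trace
#'
#' Median filter, background estimation, per-channel event detection, ladder
#' fitting and cross-channel coincidence matching, with doublet screening:
#' events longer than `doubletFactor` times the median event duration are
#' flagged, and excluded when their single-trapezoid fit residual exceeds
#' `5 x` the channel background SD (a merged doublet fits one trapezoid
#' poorly; a slow single cell does not).
#'
#' @param trace A raw [RawTrace-class].
#' @param settings A [DetectionSettings-class].
#' @param doubletFactor Duration multiple that flags a run as a potential
#'   doublet (default 3).
#' @return A list: `matched` (per-cell matched fit table, see
#'   [matchChannels()]), `fits` (per-channel fit tables), `background`,
#'   `filtered` (the filtered [RawTrace-class]) and `counts` (detected,
#'   matched, dropped, doubletFlagged, doubletExcluded).
#' @export
processTrace <- function(trace, settings = defaultDetectionSettings(),
                         doubletFactor = 3) {
  validObject(settings)
  filtered <- medianFilterTrace(trace, settings@medianWindow)
  background <- estimateBackground(filtered, settings@thresholdK)
  events <- detectEvents(filtered, settings, background)
  fits <- fitEvents(filtered, events, background)

  flagged <- 0L; excluded <- 0L
  perChannel <- lapply(seq_along(CHANNELS), function(c) {
    f <- fits[fits$channel == CHANNELS[c] & !is.na(fits$ifMv), , drop = FALSE]
    if (nrow(f) == 0) return(f)
    len <- f$endIndex - f$startIndex
    long <- len > doubletFactor * median(len)
    # 0.2 mV floor so a zero-variance (noiseless) background cannot turn
    # the residual criterion into "exclude every flagged run"
    bad <- long & f$fitResidual > pmax(5 * background$sdMv[c], 0.2)
    flagged <<- flagged + sum(long)
    excluded <<- excluded + sum(bad)
    f <- f[!bad, , drop = FALSE]
    f[order(f$tCenterS), , drop = FALSE]
  })
  matched <- matchChannels(perChannel, settings@coincidenceToleranceMs)
  list(
    matched = matched, fits = perChannel, background = background,
    filtered = filtered,
    counts = list(
      detected = as.integer(table(factor(events$channel, levels = CHANNELS))),
      matched = nrow(matched),
      dropped = attr(matched, "dropped"),
      doubletFlagged = flagged, doubletExcluded = excluded
    )
  )
}
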