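# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own vectorized code paths.

# Sliding-window median with replicate padding, naive loop.
oracleMedianFilter <- function(x, window) {
  k <- as.integer(window)
  if (k %% 2 == 0) k <- k + 1L
  h <- (k - 1L) %/% 2L
  n <- length(x)
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) median(padded[i:(i + k - 1L)]), 0)
}

# Plain scan for maximal suprathreshold runs; returns a data.frame of
# (start, end) 1-based inclusive indices of runs at least minLen long.
oracleExcursions <- function(x, threshold, minLen = 1) {
  runs <- data.frame(start = integer(0), end = integer(0))
  inRun <- FALSE
  s <- 0L
  for (i in seq_along(x)) {
    if (x[i] > threshold && !inRun) {
      inRun <- TRUE
      s <- i
    } else if (x[i] <= threshold && inRun) {
      inRun <- FALSE
      if (i - s >= minLen) runs <- rbind(runs, data.frame(start = s, end = i - 1L))
    }
  }
  if (inRun && length(x) - s + 1L >= minLen) {
    runs <- rbind(runs, data.frame(start = s, end = length(x)))
  }
  runs
}

# A trapezoid sample vector built by explicit piecewise concatenation
# (independent of the package's profile function). Durations in samples.
oracleTrapezoid <- function(amp, nRise, nPlateau, nFall, pad = 200,
                            baseline = 0) {
  rise <- if (nRise > 0) amp * seq_len(nRise) / nRise else numeric(0)
  fall <- if (nFall > 0) amp * rev(seq_len(nFall) - 1) / nFall else numeric(0)
  baseline + c(rep(0, pad), rise, rep(amp, nPlateau), fall, rep(0, pad))
}

# One-channel -> three-channel trace from a single vector.
traceFromVector <- function(x, fs = 5e5) {
  RawTrace(cbind(FITC = x, PE = x * 0, PerCP = x * 0), sampleRateHz = fs)
}

# Synthetic (n, L, 3) pulse-sequence array: per-class trapezoid shapes with
# Gaussian noise. ampMean/riseFrac are length-2 (per class) vectors.
makeShapeSequences <- function(n, L, ampMean = c(10, 10),
                               riseFrac = c(0.15, 0.35), noiseSd = 0.5,
                               seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("A", "B"), length.out = n))
  X <- array(0, dim = c(n, L, 3))
  tt <- seq(0, 1, length.out = L)
  for (i in seq_len(n)) {
    k <- as.integer(labels[i])
    rf <- riseFrac[k]
    prof <- pmin(pmin(tt / rf, 1), (1 - tt) / rf)
    prof[prof < 0] <- 0
    amp <- ampMean[k] * exp(rnorm(1, 0, 0.1))
    for (c in 1:3) {
      X[i, , c] <- amp * prof + rnorm(L, 0, noiseSd)
    }
  }
  list(X = X, labels = labels)
}
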