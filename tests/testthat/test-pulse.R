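# Pulse processing: median filter vs naive oracle, background statistics,
# detection, ladder fitting, coincidence matching.

test_that("median filter matches the sliding-window oracle", {
  # impulse rejection
  tr <- traceFromVector(c(0, 0, 10, 0, 0))
  expect_equal(traceValues(medianFilterTrace(tr, 3))[, 1], rep(0, 5))
  # constant invariance (and idempotence)
  tr <- traceFromVector(rep(5, 200))
  f1 <- medianFilterTrace(tr, 50)
  expect_equal(traceValues(f1)[, 1], rep(5, 200))
  expect_equal(traceValues(medianFilterTrace(f1, 50)),
               traceValues(f1))
  # monotone ramp is (interior-)invariant: median of monotone window = center
  ramp <- seq_len(100) / 10
  out <- traceValues(medianFilterTrace(traceFromVector(ramp), 3))[, 1]
  expect_equal(out, ramp)
  # random trace equals the brute-force oracle, replicate padding included
  set.seed(31)
  x <- rnorm(2001)
  out <- traceValues(medianFilterTrace(traceFromVector(x), 51))[, 1]
  expect_equal(out, oracleMedianFilter(x, 51))
  expect_gte(min(out), min(x))
  expect_lte(max(out), max(x))
})

test_that("median filter rejects invalid windows", {
  tr <- traceFromVector(rnorm(10))
  expect_error(medianFilterTrace(tr, 11), "longer")
})

test_that("background statistics follow the mean + k*sd rule", {
  # constant trace: sd 0, threshold = mean, flagged
  bg <- estimateBackground(traceFromVector(rep(2, 1000)))
  expect_equal(bg$meanMv[1], 2)
  expect_equal(bg$sdMv[1], 0)
  expect_equal(bg$thresholdMv[1], 2)
  expect_equal(bg$flag[1], "zero-variance")

  # exact mean 2 / sd 1 by construction -> threshold 5 at k = 3
  x <- rep(c(1, 3), 500)
  bg <- estimateBackground(traceFromVector(x))
  expect_equal(bg$meanMv[1], 2)
  expect_equal(bg$thresholdMv[1], 5, tolerance = 1e-2)

  # seeded unit Gaussian, n = 1e5
  set.seed(77)
  bg <- estimateBackground(traceFromVector(rnorm(1e5)))
  expect_lt(abs(bg$meanMv[1]), 0.02)
  expect_lt(abs(bg$sdMv[1] - 1), 0.02)
  expect_equal(bg$thresholdMv[1], 3, tolerance = 0.06)
})

test_that("event detection matches a brute-force suprathreshold scan", {
  # pure baseline -> no events
  set.seed(5)
  tr <- traceFromVector(rnorm(2e4, 5, 0.3))
  expect_equal(nrow(detectEvents(medianFilterTrace(tr))), 0)

  # a noiseless trapezoid -> one event spanning the support
  x <- oracleTrapezoid(30, 250, 1000, 250, pad = 2000)
  ev <- detectEvents(traceFromVector(x),
                     DetectionSettings(medianWindow = 1))
  expect_equal(nrow(ev), 1)
  support <- range(which(x > 0))
  expect_lte(abs(ev$startIndex[1] + 1 - support[1]), 3)
  expect_lte(abs(ev$endIndex[1] - support[2]), 3)
  expect_equal(ev$peakMv[1], 30)

  # oracle equivalence on a composite trace ~1e5 samples at SNR 20
  set.seed(91)
  x <- rnorm(1e5, 0, 1)
  starts <- seq(5000, 95000, by = 10000)
  for (s in starts) {
    x[s:(s + 1599)] <- x[s:(s + 1599)] + oracleTrapezoid(20, 300, 1000, 300,
                                                          pad = 0)
  }
  tr <- medianFilterTrace(traceFromVector(x), 50)
  bg <- estimateBackground(tr)
  ev <- detectEvents(tr, DetectionSettings(), bg)
  runs <- oracleExcursions(traceValues(tr)[, 1], bg$thresholdMv[1],
                           minLen = 250)
  expect_equal(nrow(ev), length(starts))
  expect_equal(nrow(ev), nrow(runs))
  # every oracle run lies inside the matching (boundary-extended) event
  expect_true(all(runs$start >= ev$startIndex + 1 - 60))
  expect_true(all(runs$end <= ev$endIndex + 60))
})

test_that("detection at SNR 20 recovers exactly the injected cells", {
  p <- a549Params()
  cells <- samplePopulation(p, 20, seed = 21)
  cfg <- defaultChannelConfig()
  tr <- medianFilterTrace(renderTrace(cells, cfg, seed = 22))
  ev <- detectEvents(tr)
  expect_equal(as.integer(table(ev$channel)), c(20L, 20L, 20L))
})

test_that("ladder fit recovers noiseless trapezoids to one sample period", {
  fs <- 5e5
  x <- oracleTrapezoid(30, 250, 1000, 250, pad = 400) # 0.5/2/0.5 ms
  f <- fitLadder(x, fs)
  expect_true(f$converged)
  expect_equal(f$taMs, 0.5, tolerance = 1 / fs * 1e3 / 0.5)
  expect_equal(f$tsMs, 2.0, tolerance = 1 / fs * 1e3 / 2.0)
  expect_equal(f$tdMs, 0.5, tolerance = 1 / fs * 1e3 / 0.5)
  expect_lt(abs(f$ifMv - 30), 0.1)
  expect_lt(f$fitResidual, 0.05)

  # asymmetric case
  x <- oracleTrapezoid(12, 100, 800, 400, pad = 300)
  f <- fitLadder(x, fs)
  expect_equal(f$taMs, 0.2, tolerance = 0.01)
  expect_equal(f$tdMs, 0.8, tolerance = 0.01)
  expect_lt(abs(f$ifMv - 12), 0.1)

  # rectangle: rise/fall below one sample period, amplitude exact
  x <- oracleTrapezoid(25, 0, 1000, 0, pad = 300)
  f <- fitLadder(x, fs)
  expect_lte(f$taMs, 1e3 / fs + 1e-9)
  expect_lte(f$tdMs, 1e3 / fs + 1e-9)
  expect_lt(abs(f$ifMv - 25), 0.1)
})

test_that("ladder fit is unbiased under noise (Monte-Carlo)", {
  fs <- 5e5
  base <- oracleTrapezoid(30, 250, 1000, 250, pad = 300)
  set.seed(55)
  fits <- do.call(rbind, lapply(1:200, function(i) {
    fitLadder(base + rnorm(length(base), 0, 2), fs)
  }))
  expect_true(all(fits$converged))
  semIf <- sd(fits$ifMv) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$ifMv) - 30), 3 * semIf)
  semTs <- sd(fits$tsMs) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$tsMs) - 2), max(3 * semTs, 2e3 / fs))
})

test_that("coincidence matching pairs channels and counts drops", {
  mkFit <- function(tc) {
    data.frame(taMs = 1, tsMs = 2, tdMs = 1, ifMv = 10, fitResidual = 0.1,
               startIndex = 0, endIndex = 10, tCenterS = tc)
  }
  # identical timestamps -> all matched
  f <- lapply(1:3, function(c) do.call(rbind, lapply(c(0.01, 0.05, 0.09),
                                                     mkFit)))
  m <- matchChannels(f, toleranceMs = 1)
  expect_equal(nrow(m), 3)
  expect_equal(attr(m, "dropped"), c(0L, 0L, 0L))

  # an event in one channel only is dropped and counted
  f2 <- f
  f2[[2]] <- rbind(f2[[2]], mkFit(0.5))
  m <- matchChannels(f2, toleranceMs = 1)
  expect_equal(nrow(m), 3)
  expect_equal(attr(m, "dropped"), c(0L, 1L, 0L))

  # +-0.2 ms jitter within a 1 ms tolerance -> all matched
  set.seed(8)
  tc <- seq(0.02, 0.5, by = 0.03)
  f3 <- lapply(1:3, function(c) {
    do.call(rbind, lapply(tc + runif(length(tc), -2e-4, 2e-4), mkFit))
  })
  m <- matchChannels(f3, toleranceMs = 1)
  expect_equal(nrow(m), length(tc))

  # beyond tolerance -> not matched
  f4 <- list(mkFit(0.01), mkFit(0.015), mkFit(0.01))
  expect_equal(nrow(matchChannels(f4, toleranceMs = 1)), 0)
})

test_that("processTrace keeps slow single cells but flags long runs", {
  # one slow cell (long pulse) among normal ones must survive the doublet
  # screen: it fits a single trapezoid at noise level
  cells <- groundTruthCells(
    arrivalTimeS = c(0.005, 0.1, 0.15, 0.2),
    copies = matrix(rep(c(2e6, 6e3, 8e4), each = 4), ncol = 3),
    diameterUm = rep(15, 4),
    velocityUmPerMs = c(2, 15, 15, 15) # first cell ~12x slower
  )
  tr <- renderTrace(cells, defaultChannelConfig(), seed = 3)
  res <- processTrace(tr)
  expect_equal(res$counts$matched, 4)
  expect_gte(res$counts$doubletFlagged, 1)
  expect_equal(res$counts$doubletExcluded, 0)
})
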