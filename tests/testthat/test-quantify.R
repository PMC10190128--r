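# Quantification: volume arithmetic, calibration fitting, compensation,
# intensity -> copies, kinematic inversion, and the full round trip.

test_that("molecule counts follow concentration x volume x Avogadro", {
  g <- GeometryModel(60, 400)
  expect_equal(detectionVolumeL(g), 2.4e-11) # 60 x 20 x 20 um^3
  expect_equal(moleculesInVolume(0, g), 0)
  expect_equal(moleculesInVolume(1e-9, g), 1e-9 * 2.4e-11 * 6.02214076e23,
               tolerance = 1e-12)
  expect_equal(moleculesInVolume(1e-9, g), 1.4453e4, tolerance = 1e-4)
  # a 1:100 dilution of a 100 nM stock equals 1 nM
  expect_equal(moleculesInVolume(100e-9 / 100, g), moleculesInVolume(1e-9, g))
  expect_error(moleculesInVolume(-1e-9, g), ">= 0")
})

test_that("calibration line fitting is exact on exact data and validated", {
  pts <- data.frame(nMolecules = c(1, 2, 5, 10), intensityMv = NA)
  pts$intensityMv <- 2 * pts$nMolecules + 1
  cu <- fitCalibrationCurve(pts)
  expect_equal(cu@slope, 2, tolerance = 1e-12)
  expect_equal(cu@intercept, 1, tolerance = 1e-12)
  expect_equal(cu@rSquared, 1, tolerance = 1e-12)

  expect_error(fitCalibrationCurve(pts[1, ]), "calibration error")
  bad <- pts
  bad$intensityMv <- 10 - 2 * bad$nMolecules
  expect_error(fitCalibrationCurve(bad), "non-positive slope")
})

test_that("noiseless dilution series recovers the configured gain exactly", {
  cfg <- ChannelConfig(defaultChannelConfig()@gain, baselineMv = 5,
                       noiseSdMv = 0)
  for (c in 1:3) {
    series <- renderCalibrationSeries(calibrationDilutions(),
                                      defaultStockConcentrations()[c], cfg,
                                      seed = c, channel = c)
    cu <- calibrateFromTraces(series, channel = c)
    expect_equal(cu@slope, cfg@gain[c], tolerance = 1e-9)
    expect_lt(abs(cu@intercept), 1e-9)
    expect_equal(cu@rSquared, 1, tolerance = 1e-12)
  }
})

test_that("noisy calibration slope is within 3 SE of the truth", {
  set.seed(12)
  nRep <- 50
  nMol <- rep(c(1e4, 2e4, 5e4, 1e5, 2e5, 5e5), each = nRep)
  pts <- data.frame(nMolecules = nMol,
                    intensityMv = 3e-4 * nMol + rnorm(length(nMol), 0, 1))
  cu <- fitCalibrationCurve(pts)
  se <- summary(lm(intensityMv ~ nMolecules, pts))$coefficients[2, 2]
  expect_lt(abs(cu@slope - 3e-4), 3 * se)
})

test_that("compensation inverts any invertible spillover", {
  expect_equal(applyCompensation(c(10, 20, 30), diag(3)), c(10, 20, 30))
  sp <- spilloverPreset()
  truth <- c(25, 80, 12)
  mixed <- as.numeric(sp %*% truth)
  expect_equal(applyCompensation(mixed, sp), truth, tolerance = 1e-9)
  # matrix form
  M <- rbind(truth, 2 * truth)
  expect_equal(applyCompensation(t(apply(M, 1, function(r) sp %*% r)), sp),
               unname(M), tolerance = 1e-9, ignore_attr = TRUE)
  singular <- matrix(1, 3, 3)
  expect_error(applyCompensation(c(1, 2, 3), singular), "singular")
})

test_that("intensity -> copies inverts the calibration line with clipping", {
  cu <- fitCalibrationCurve(data.frame(nMolecules = c(0, 1e5),
                                       intensityMv = c(0, 100)))
  expect_equal(as.numeric(intensityToCopies(0, cu)), 0)
  expect_equal(as.numeric(intensityToCopies(29.7, cu)), 29700)
  neg <- intensityToCopies(-5, cu)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "clipped"))
  # round trip through the forward gain map
  copies <- c(1e4, 5e5, 2e6)
  expect_equal(as.numeric(intensityToCopies(copies * 1e-3,
    fitCalibrationCurve(data.frame(nMolecules = c(0, 1e6),
                                   intensityMv = c(0, 1e3))))),
    copies, tolerance = 1e-9)
})

test_that("kinematic inversion matches the closed form and its limits", {
  g <- GeometryModel(60, 400)
  k <- kinematicsFromPulse(1, 2, 1, g)
  expect_equal(k$velocityUmPerMs, 20)
  expect_equal(k$diameterUm, 20)
  expect_equal(k$transitMs, 4)
  # vanishing rise time: point-like cell at v = window / Ts
  k <- kinematicsFromPulse(1e-9, 3, 1e-9, g)
  expect_equal(k$velocityUmPerMs, 20, tolerance = 1e-6)
  expect_lt(k$diameterUm, 1e-6)
  # zero duration flagged
  k <- kinematicsFromPulse(0, 0, 0, g)
  expect_true(k$flagged)
})

test_that("noiseless generator round trip recovers per-cell kinematics", {
  p <- a549Params()
  cells <- samplePopulation(p, 50, seed = 33)
  cfg <- ChannelConfig(defaultChannelConfig()@gain, baselineMv = 5,
                       noiseSdMv = 0)
  res <- detectAndFitCells(cells, cfg, seed = 34)
  expect_equal(nrow(res$matched), 50)
  curves <- buildCalibrationCurves(cfg, seed = 35)
  rec <- quantifyCells(res$matched, curves)
  # records and cells are both time-ordered
  expect_equal(rec$velocityUmPerMs, cells$velocityUmPerMs, tolerance = 5e-3)
  expect_equal(rec$diameterUm, cells$diameterUm, tolerance = 2e-2)
  expect_equal(rec$copiesFitc, cells$copiesFitc, tolerance = 1e-3)
  expect_equal(rec$copiesPe, cells$copiesPe, tolerance = 1e-2)
})

test_that("full quantification round trip at SNR >= 20 is within 2% per cell", {
  # amplitudes kept >= 30 mV (20x the 1.5 mV noise) by a tight copy spread
  p <- PopulationParams("bright", copiesMean = c(3e6, 1e4, 1.5e5),
                        copiesSd = c(3e5, 1e3, 1.5e4),
                        diameterMean = 15.2, diameterSd = 2,
                        velocityMean = 16, velocitySd = 4)
  cells <- samplePopulation(p, 100, seed = 61)
  cfg <- defaultChannelConfig()
  res <- detectAndFitCells(cells, cfg, seed = 62)
  expect_equal(nrow(res$matched), 100)
  curves <- buildCalibrationCurves(
    ChannelConfig(cfg@gain, cfg@baselineMv, 0), seed = 63)
  rec <- quantifyCells(res$matched, curves)
  for (col in c("copiesFitc", "copiesPe", "copiesPercp")) {
    relErr <- abs(rec[[col]] / cells[[col]] - 1)
    expect_lt(max(relErr), 0.02)
    sem <- sd(cells[[col]]) / sqrt(nrow(cells))
    expect_lt(abs(mean(rec[[col]]) - mean(cells[[col]])), 3 * sem)
  }
})

test_that("spillover mixing + compensation is the identity end to end", {
  sp <- spilloverPreset()
  cfg <- ChannelConfig(defaultChannelConfig()@gain, baselineMv = 5,
                       noiseSdMv = 0, spillover = sp)
  cells <- samplePopulation(a549Params(), 20, seed = 71)
  res <- detectAndFitCells(cells, cfg, seed = 72)
  curves <- buildCalibrationCurves(
    ChannelConfig(cfg@gain, 5, 0), seed = 73) # unmixed reference curves
  rec <- quantifyCells(res$matched, curves, spillover = sp)
  expect_equal(rec$copiesFitc, cells$copiesFitc, tolerance = 1e-3)
  expect_equal(rec$copiesPe, cells$copiesPe, tolerance = 1e-2)
  expect_equal(rec$copiesPercp, cells$copiesPercp, tolerance = 1e-2)
})
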