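# Classification: splitting, evaluation, the feedforward net, the LSTM
# (including an exact-gradient check), and the hyperparameter screen.

test_that("stratified split honours fractions, disjointness and the seed", {
  labels <- factor(rep(c("A", "B"), each = 100))
  sp <- splitDataset(labels, c(0.70, 0.15, 0.15), seed = 4)
  expect_equal(length(sp$train), 140)
  expect_equal(length(sp$validation), 30)
  expect_equal(length(sp$test), 30)
  for (lv in c("A", "B")) {
    expect_equal(sum(labels[sp$train] == lv), 70)
    expect_equal(sum(labels[sp$test] == lv), 15)
  }
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(sort(unlist(sp)), 1:200, ignore_attr = TRUE)
  expect_identical(splitDataset(labels, seed = 4), sp)
  expect_error(splitDataset(factor(c("A", "A", "A", "B", "B"))), "at least 3")
})

test_that("split sizes on the published cohort follow the floor rule", {
  labels <- factor(c(rep("A549", 10232), rep("CAL27", 16376)))
  sp <- splitDataset(labels, seed = 1)
  # brute-force expectation per class: floor(0.7 n), floor(0.15 n), rest
  expTrain <- floor(0.7 * 10232) + floor(0.7 * 16376)
  expVal <- floor(0.15 * 10232) + floor(0.15 * 16376)
  expect_equal(length(sp$train), expTrain)
  expect_equal(length(sp$validation), expVal)
  expect_equal(length(sp$test), 26608 - expTrain - expVal)
  # every class within one item of the exact fraction
  for (lv in levels(labels)) {
    n <- sum(labels == lv)
    expect_lte(abs(sum(labels[sp$train] == lv) - 0.7 * n), 1)
    expect_lte(abs(sum(labels[sp$test] == lv) - 0.15 * n), 1 + 1)
  }
})

test_that("evaluation produces exact confusion counts", {
  ev <- evaluateClassifier(c("A", "A", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(ev$accuracy, 1)
  expect_equal(diag(ev$confusion), c(A = 2, B = 2))

  ev <- evaluateClassifier(rep("A", 10), rep(c("A", "B"), 5),
                           classLevels = c("A", "B"))
  expect_equal(ev$accuracy, 0.5)

  # a listed pair vs a hand tally
  pred <- c("A", "B", "B", "A", "A", "B", "A", "A", "B", "B")
  truth <- c("A", "A", "B", "A", "B", "B", "A", "B", "B", "A")
  ev <- evaluateClassifier(pred, truth, classLevels = c("A", "B"))
  tally <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  for (i in 1:10) tally[truth[i], pred[i]] <- tally[truth[i], pred[i]] + 1
  expect_equal(unname(ev$confusion), unname(tally))
  expect_equal(ev$accuracy, sum(pred == truth) / 10)
  expect_equal(sum(ev$confusion), 10)
  expect_error(evaluateClassifier(pred[1:5], truth), "equal length")
})

test_that("the feedforward net separates well-separated classes", {
  set.seed(10)
  n <- 400
  x <- cbind(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 20)), # 20 SD apart
             f2 = rnorm(n), f3 = rnorm(n))
  labels <- factor(rep(c("A", "B"), each = n / 2))
  rep <- trainFFNN(x, labels, TrainConfig(hiddenUnitsFfnn = 10,
                                          maxEpochs = 20, seed = 2))
  expect_gte(reportAccuracy(rep, "test"), 0.99)
  expect_equal(sum(reportConfusion(rep)), length(splitDataset(labels,
    seed = childSeed(2, 1))$test))
})

test_that("identical class distributions give chance-level accuracy", {
  set.seed(20)
  n <- 2000
  x <- matrix(rnorm(3 * n), ncol = 3)
  labels <- factor(rep(c("A", "B"), each = n / 2))
  rep <- trainFFNN(x, labels, TrainConfig(hiddenUnitsFfnn = 10,
                                          maxEpochs = 10, seed = 3))
  expect_gte(reportAccuracy(rep, "test"), 0.45)
  expect_lte(reportAccuracy(rep, "test"), 0.55)
})

test_that("adding a strongly separating feature never hurts accuracy", {
  set.seed(30)
  n <- 600
  weak <- matrix(rnorm(2 * n), ncol = 2)
  labels <- factor(rep(c("A", "B"), each = n / 2))
  strong <- cbind(weak, sep = c(rnorm(n / 2, 0), rnorm(n / 2, 15)))
  cfg <- TrainConfig(hiddenUnitsFfnn = 8, maxEpochs = 15, seed = 5)
  accWeak <- reportAccuracy(trainFFNN(weak, labels, cfg), "test")
  accStrong <- reportAccuracy(trainFFNN(strong, labels, cfg), "test")
  expect_gte(accStrong, accWeak)
  expect_gte(accStrong, 0.99)
})

test_that("LSTM backpropagation matches numerical gradients", {
  set.seed(40)
  B <- 3; L <- 5; C <- 2; H <- 4
  X <- array(rnorm(B * L * C), dim = c(B, L, C))
  y <- c(1L, 2L, 1L)
  params <- flowLadder:::lstmInit(C, H, seed = 41)
  lossAt <- function(p) {
    fwd <- flowLadder:::lstmForward(p, X)
    flowLadder:::softmaxLoss(fwd$logits, y)$loss
  }
  fwd <- flowLadder:::lstmForward(params, X, keepCache = TRUE)
  sl <- flowLadder:::softmaxLoss(fwd$logits, y)
  grads <- flowLadder:::lstmBackward(params, fwd, sl$dlogits)
  eps <- 1e-6
  for (nm in c("W", "b", "Wy", "by")) {
    idx <- seq_len(min(length(params[[nm]]), 25))
    for (i in idx) {
      pPlus <- params; pPlus[[nm]][i] <- pPlus[[nm]][i] + eps
      pMinus <- params; pMinus[[nm]][i] <- pMinus[[nm]][i] - eps
      num <- (lossAt(pPlus) - lossAt(pMinus)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("LSTM learns amplitude-separated classes and fails shuffled labels", {
  sep <- makeShapeSequences(400, 32, ampMean = c(5, 50),
                            riseFrac = c(0.2, 0.2), seed = 50)
  cfg <- TrainConfig(lstmHidden = 8, batchSize = 50, learningRate = 0.01,
                     maxEpochs = 10, seqLength = 32, seed = 6)
  rep <- trainLSTM(sep$X, sep$labels, cfg)
  expect_gte(reportAccuracy(rep, "test"), 0.99)
  expect_true(all(rep@trace$validation <= 1 & rep@trace$validation >= 0))

  # destroyed signal: shuffled labels -> chance
  set.seed(51)
  shuffled <- sample(sep$labels)
  rep2 <- trainLSTM(sep$X, shuffled, cfg)
  expect_gte(reportAccuracy(rep2, "test"), 0.40)
  expect_lte(reportAccuracy(rep2, "test"), 0.60)
})

test_that("LSTM training is seed-reproducible", {
  sep <- makeShapeSequences(200, 16, ampMean = c(5, 20), seed = 52)
  cfg <- TrainConfig(lstmHidden = 6, batchSize = 50, learningRate = 0.01,
                     maxEpochs = 4, seqLength = 16, seed = 9)
  r1 <- trainLSTM(sep$X, sep$labels, cfg)
  r2 <- trainLSTM(sep$X, sep$labels, cfg)
  expect_identical(r1@accuracy, r2@accuracy)
  expect_identical(r1@confusion, r2@confusion)
})

test_that("the hyperparameter screen is consistent with direct training", {
  sep <- makeShapeSequences(200, 16, ampMean = c(5, 25), seed = 53)
  cfg <- TrainConfig(lstmHidden = 6, batchSize = 50, learningRate = 0.01,
                     maxEpochs = 3, seqLength = 16, seed = 11)
  tab <- hyperparameterScreen(sep$X, sep$labels, batchSizes = 50,
                              learningRates = 0.01, hiddenUnits = 6,
                              cfg = cfg)
  expect_equal(nrow(tab), 1)
  direct <- trainLSTM(sep$X, sep$labels, cfg)
  expect_equal(tab$testAccuracy, reportAccuracy(direct, "test"))

  # two seeds on a separable problem agree to < 0.05
  cfg2 <- cfg; cfg2@seed <- 12
  tab2 <- hyperparameterScreen(sep$X, sep$labels, batchSizes = 50,
                               learningRates = 0.01, hiddenUnits = 6,
                               cfg = cfg2)
  expect_lt(abs(tab$testAccuracy - tab2$testAccuracy), 0.05)
})

test_that("the full screening grid runs and reports sane accuracies", {
  sep <- makeShapeSequences(120, 16, ampMean = c(5, 25), seed = 54)
  cfg <- TrainConfig(maxEpochs = 1, seqLength = 16, seed = 13)
  tab <- hyperparameterScreen(sep$X, sep$labels, cfg = cfg)
  expect_equal(nrow(tab), 27)
  expect_true(all(tab$testAccuracy >= 0 & tab$testAccuracy <= 1))
  expect_true(all(tab$epochsToConvergence >= 1))
  expect_length(attr(tab, "traces"), 27)
})
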