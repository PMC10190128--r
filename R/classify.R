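# Cell-type classification: a two-layer feedforward network on the three
# quantified protein features and an LSTM on raw fixed-length pulse
# sequences, with stratified 70/15/15 splitting and a hyperparameter screen.

#' Stratified train/validation/test split
#'
#' Disjoint partition stratified by label: within each class, `floor(f1 n)`
#' items go to training, `floor(f2 n)` to validation and the remainder to
#' testing, after a seeded shuffle, so per-class sizes are within one item
#' of the exact fractions.
#'
#' @param labels Factor (or coercible) class label per item.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed RNG seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(labels, fractions = c(0.70, 0.15, 0.15),
                         seed = 1L) {
  labels <- as.factor(labels)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    stop("fractions must be positive and sum to 1")
  }
  if (any(table(labels) < 3)) {
    stop("split error: every class needs at least 3 members")
  }
  set.seed(seed)
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (lv in levels(labels)) {
    members <- sample(which(labels == lv))
    n <- length(members)
    nTr <- floor(fractions[1] * n)
    nVa <- floor(fractions[2] * n)
    idx$train <- c(idx$train, members[seq_len(nTr)])
    idx$validation <- c(idx$validation, members[nTr + seq_len(nVa)])
    idx$test <- c(idx$test, members[(nTr + nVa + 1):n])
  }
  lapply(idx, sort)
}

#' Accuracy and confusion matrix of predictions
#'
#' @param predictions Predicted labels (factor or coercible).
#' @param labels True labels.
#' @param classLevels Fixed class order for the confusion matrix; defaults
#'   to the levels of `labels`.
#' @return List with `accuracy` and `confusion` (rows = truth,
#'   columns = prediction).
#' @export
evaluateClassifier <- function(predictions, labels, classLevels = NULL) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  if (is.null(classLevels)) classLevels <- levels(as.factor(labels))
  truth <- factor(labels, levels = classLevels)
  pred <- factor(predictions, levels = classLevels)
  confusion <- table(truth = truth, prediction = pred)
  confusion <- matrix(as.integer(confusion), nrow = length(classLevels),
                      dimnames = list(truth = classLevels,
                                      prediction = classLevels))
  list(accuracy = sum(diag(confusion)) / length(labels),
       confusion = confusion)
}

# z-score columns by the given center/scale; zero scales pass through.
standardizeBy <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Train the feedforward protein-feature classifier
#'
#' One hidden layer (`hiddenUnitsFfnn` logistic units, default 50) and a
#' two-unit softmax output on z-scored features, trained in stages with the
#' best validation-accuracy checkpoint kept (early stopping with
#' `patience`). Features are standardized with training-split statistics.
#'
#' @param features Numeric matrix or data.frame of per-cell features
#'   (e.g. the three protein copy numbers).
#' @param labels Two-class factor (or coercible) of cell types.
#' @param cfg A [TrainConfig-class].
#' @return A [ClassifierReport-class] (`model = "ffnn"`).
#' @export
trainFFNN <- function(features, labels, cfg = TrainConfig()) {
  validObject(cfg)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("two classes required")
  if (anyNA(x)) stop("features must not contain missing values")
  split <- splitDataset(labels, cfg@fractions, seed = childSeed(cfg@seed, 1))
  center <- colMeans(x[split$train, , drop = FALSE])
  scl <- apply(x[split$train, , drop = FALSE], 2, sd)
  xs <- standardizeBy(x, center, scl)
  yMat <- nnet::class.ind(labels)

  stageIters <- 20L
  set.seed(childSeed(cfg@seed, 2))
  net <- NULL
  best <- list(acc = -Inf, net = NULL)
  sinceBest <- 0L
  traceRows <- list()
  accOn <- function(net, idx) {
    p <- max.col(predict(net, xs[idx, , drop = FALSE]), ties.method = "first")
    mean(levels(labels)[p] == labels[idx])
  }
  for (stage in seq_len(as.integer(cfg@maxEpochs))) {
    args <- list(x = xs[split$train, , drop = FALSE],
                 y = yMat[split$train, , drop = FALSE],
                 size = as.integer(cfg@hiddenUnitsFfnn), softmax = TRUE,
                 maxit = stageIters, decay = 1e-4, trace = FALSE,
                 MaxNWts = 1e5)
    if (!is.null(net)) args$Wts <- net$wts
    net <- do.call(nnet::nnet, args)
    va <- accOn(net, split$validation)
    traceRows[[stage]] <- data.frame(epoch = stage,
                                     train = accOn(net, split$train),
                                     validation = va)
    if (va > best$acc + 1e-9) {
      best <- list(acc = va, net = net)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= cfg@patience) break
    }
  }
  flags <- if (is.null(best$net)) "non-convergence" else character(0)
  if (is.null(best$net)) best$net <- net
  predAll <- levels(labels)[max.col(predict(best$net, xs),
                                    ties.method = "first")]
  buildReport("ffnn", predAll, labels, split, cfg,
              do.call(rbind, traceRows), flags)
}

# Shared report assembly for both classifiers.
buildReport <- function(model, predAll, labels, split, cfg, traceDf, flags) {
  accs <- vapply(split, function(idx) mean(predAll[idx] == labels[idx]), 0)
  ev <- evaluateClassifier(predAll[split$test], labels[split$test],
                           classLevels = levels(labels))
  new("ClassifierReport", model = model,
      accuracy = c(train = unname(accs["train"]),
                   validation = unname(accs["validation"]),
                   test = unname(accs["test"]),
                   overall = mean(predAll == labels)),
      confusion = ev$confusion, trace = traceDf, config = cfg,
      flags = flags)
}

#' Resample a pulse matrix to fixed length
#'
#' Linear interpolation of each channel onto `L` evenly spaced points over
#' the segment, the fixed-shape input the LSTM expects.
#'
#' @param segment Numeric matrix, samples x channels.
#' @param L Target length.
#' @return An `L` x channels matrix.
#' @export
resamplePulse <- function(segment, L) {
  segment <- as.matrix(segment)
  n <- nrow(segment)
  if (n == 1) return(matrix(rep(segment, each = L), nrow = L))
  at <- seq(1, n, length.out = L)
  apply(segment, 2, function(col) approx(seq_len(n), col, xout = at)$y)
}

#' Extract fixed-length pulse sequences for matched cells
#'
#' For each matched cell, cuts the union of the three channels' fitted
#' event supports out of the filtered trace and resamples it to `L`
#' samples per channel.
#'
#' @param filtered The filtered [RawTrace-class] (from [processTrace()]).
#' @param matched Matched fit table (from [processTrace()]).
#' @param L Fixed sequence length (e.g. `TrainConfig()@seqLength`).
#' @return Numeric array `(nCells, L, 3)`.
#' @export
extractPulses <- function(filtered, matched, L = 256) {
  x <- traceValues(filtered)
  n <- nrow(matched)
  out <- array(0, dim = c(n, L, 3))
  for (i in seq_len(n)) {
    s <- min(matched$startIndex1[i], matched$startIndex2[i],
             matched$startIndex3[i]) + 1L
    e <- max(matched$endIndex1[i], matched$endIndex2[i],
             matched$endIndex3[i])
    out[i, , ] <- resamplePulse(x[s:e, , drop = FALSE], L)
  }
  out
}

#' Train the LSTM pulse-shape classifier
#'
#' Six-stage sequence classifier (sequence input, LSTM with
#' `lstmHidden` units, dropout, dense, softmax, class output) trained with
#' mini-batch Adam at `learningRate` and `batchSize`, per-channel z-scoring
#' by training-split statistics, and early stopping on validation accuracy.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param sequences Numeric array `(n, L, 3)` of fixed-length pulses.
#' @param labels Two-class factor of cell types.
#' @param cfg A [TrainConfig-class].
#' @param dropout Dropout rate on the LSTM output (default 0.2).
#' @return A [ClassifierReport-class] (`model = "lstm"`).
#' @export
trainLSTM <- function(sequences, labels, cfg = TrainConfig(),
                      dropout = 0.2) {
  validObject(cfg)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("two classes required")
  stopifnot(length(dim(sequences)) == 3, dim(sequences)[1] == length(labels))
  if (any(!is.finite(sequences))) stop("sequences must be finite")
  split <- splitDataset(labels, cfg@fractions, seed = childSeed(cfg@seed, 3))
  # per-channel z-score from training-split statistics
  for (c in seq_len(dim(sequences)[3])) {
    tr <- sequences[split$train, , c]
    m <- mean(tr); s <- sd(as.numeric(tr))
    if (s == 0) s <- 1
    sequences[, , c] <- (sequences[, , c] - m) / s
  }
  yIdx <- as.integer(labels)
  H <- as.integer(cfg@lstmHidden)
  params <- lstmInit(dim(sequences)[3], H, nClasses = 2,
                     seed = childSeed(cfg@seed, 4))
  state <- adamInit(params)
  nTr <- length(split$train)
  bs <- min(as.integer(cfg@batchSize), nTr)
  best <- list(acc = -Inf, params = params)
  sinceBest <- 0L
  traceRows <- list()
  set.seed(childSeed(cfg@seed, 5))
  for (epoch in seq_len(as.integer(cfg@maxEpochs))) {
    order <- sample(split$train)
    for (s0 in seq(1, nTr, by = bs)) {
      batch <- order[s0:min(s0 + bs - 1L, nTr)]
      Xb <- sequences[batch, , , drop = FALSE]
      mask <- if (dropout > 0) {
        matrix(rbinom(length(batch) * H, 1, 1 - dropout) / (1 - dropout),
               length(batch), H)
      } else NULL
      fwd <- lstmForward(params, Xb, dropoutMask = mask, keepCache = TRUE)
      sl <- softmaxLoss(fwd$logits, yIdx[batch])
      if (!is.finite(sl$loss)) {
        stop(sprintf("lstm training diverged (non-finite loss, epoch %d)",
                     epoch))
      }
      grads <- lstmBackward(params, fwd, sl$dlogits, dropoutMask = mask)
      upd <- adamStep(params, grads, state, lr = cfg@learningRate)
      params <- upd$params; state <- upd$state
    }
    accOn <- function(idx) {
      mean(lstmPredict(params,
                       sequences[idx, , , drop = FALSE]) == yIdx[idx])
    }
    va <- accOn(split$validation)
    traceRows[[epoch]] <- data.frame(epoch = epoch,
                                     train = accOn(split$train),
                                     validation = va)
    if (va > best$acc + 1e-9) {
      best <- list(acc = va, params = params)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= cfg@patience) break
    }
  }
  predAll <- levels(labels)[lstmPredict(best$params, sequences)]
  buildReport("lstm", predAll, labels, split, cfg,
              do.call(rbind, traceRows), character(0))
}

#' Screen LSTM hyperparameters over a grid
#'
#' Trains one model per grid point (all combinations of the supplied batch
#' sizes, learning rates and hidden widths) with a shared seed and returns
#' a comparison table; accuracy-vs-epoch traces are attached as the
#' `traces` attribute.
#'
#' @param sequences Numeric array `(n, L, 3)`.
#' @param labels Two-class factor.
#' @param batchSizes,learningRates,hiddenUnits Grid values (defaults are the
#'   standard screening grid: 10/100/1000, 0.01/0.001/0.0001, 64/128/256).
#' @param cfg Base [TrainConfig-class]; each grid point overrides its
#'   batch size, learning rate and hidden width.
#' @param dropout Dropout rate passed to [trainLSTM()].
#' @return `data.frame` with one row per grid point: `batchSize`,
#'   `learningRate`, `hiddenUnits`, `testAccuracy`, `epochsToConvergence`.
#' @export
hyperparameterScreen <- function(sequences, labels,
                                 batchSizes = c(10, 100, 1000),
                                 learningRates = c(0.01, 0.001, 0.0001),
                                 hiddenUnits = c(64, 128, 256),
                                 cfg = TrainConfig(), dropout = 0.2) {
  grid <- expand.grid(batchSize = batchSizes, learningRate = learningRates,
                      hiddenUnits = hiddenUnits)
  traces <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gcfg <- cfg
    gcfg@batchSize <- grid$batchSize[i]
    gcfg@learningRate <- grid$learningRate[i]
    gcfg@lstmHidden <- grid$hiddenUnits[i]
    rep <- trainLSTM(sequences, labels, gcfg, dropout = dropout)
    traces[[i]] <<- rep@trace
    data.frame(
      batchSize = grid$batchSize[i], learningRate = grid$learningRate[i],
      hiddenUnits = grid$hiddenUnits[i],
      testAccuracy = reportAccuracy(rep, "test"),
      epochsToConvergence = rep@trace$epoch[which.max(rep@trace$validation)]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "traces") <- traces
  out
}
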