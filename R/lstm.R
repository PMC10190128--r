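# A compact LSTM sequence classifier written with base matrix algebra:
# sequence input -> LSTM -> dropout -> dense -> softmax -> class. Written in
# package code so the recurrent classifier is fully inspectable and
# deterministic; gradients are exact BPTT and are checked against numerical
# differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Parameter container. Gate blocks in W/b order: input, forget, cell, output.
lstmInit <- function(nInput, nHidden, nClasses = 2, seed = 1L) {
  set.seed(seed)
  s <- 1 / sqrt(nHidden)
  W <- matrix(runif(4 * nHidden * (nInput + nHidden), -s, s),
              nrow = 4 * nHidden)
  b <- rep(0, 4 * nHidden)
  b[(nHidden + 1):(2 * nHidden)] <- 1 # forget-gate bias at 1 (standard)
  Wy <- matrix(runif(nClasses * nHidden, -s, s), nrow = nClasses)
  by <- rep(0, nClasses)
  list(W = W, b = b, Wy = Wy, by = by, nHidden = nHidden, nInput = nInput)
}

# X: array (batch, time, channels). Returns logits and (optionally) the
# per-step caches needed for BPTT.
lstmForward <- function(params, X, dropoutMask = NULL, keepCache = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  H <- params$nHidden
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keepCache) vector("list", L) else NULL
  iH <- 1:H; fH <- H + iH; gH <- 2 * H + iH; oH <- 3 * H + iH
  for (t in seq_len(L)) {
    xt <- matrix(X[, t, ], nrow = B, ncol = C)
    z <- cbind(xt, h) %*% t(params$W) +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    gi <- sigmoid(z[, iH, drop = FALSE])
    gf <- sigmoid(z[, fH, drop = FALSE])
    gg <- tanh(z[, gH, drop = FALSE])
    go <- sigmoid(z[, oH, drop = FALSE])
    cPrev <- cc
    cc <- gf * cPrev + gi * gg
    tc <- tanh(cc)
    hPrev <- h
    h <- go * tc
    if (keepCache) {
      cache[[t]] <- list(xt = xt, hPrev = hPrev, cPrev = cPrev,
                         gi = gi, gf = gf, gg = gg, go = go, cc = cc, tc = tc)
    }
  }
  hDrop <- if (is.null(dropoutMask)) h else h * dropoutMask
  logits <- hDrop %*% t(params$Wy) + matrix(params$by, B, length(params$by),
                                            byrow = TRUE)
  list(logits = logits, h = h, hDrop = hDrop, cache = cache)
}

# Row-wise softmax probabilities.
softmaxProb <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy loss and its gradient wrt logits. yIdx: 1-based class.
softmaxLoss <- function(logits, yIdx) {
  p <- softmaxProb(logits)
  B <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(B), yIdx)], 1e-12)))
  d <- p
  d[cbind(seq_len(B), yIdx)] <- d[cbind(seq_len(B), yIdx)] - 1
  list(loss = loss, dlogits = d / B)
}

# Exact BPTT gradients for one mini-batch.
lstmBackward <- function(params, fwd, dlogits, dropoutMask = NULL) {
  H <- params$nHidden
  cache <- fwd$cache
  L <- length(cache)
  B <- nrow(dlogits)
  iH <- 1:H; fH <- H + iH; gH <- 2 * H + iH; oH <- 3 * H + iH

  dWy <- t(dlogits) %*% fwd$hDrop
  dby <- colSums(dlogits)
  dh <- dlogits %*% params$Wy
  if (!is.null(dropoutMask)) dh <- dh * dropoutMask
  dc <- matrix(0, B, H)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  db <- rep(0, length(params$b))
  Wx <- params$W[, seq_len(params$nInput), drop = FALSE]
  Wh <- params$W[, params$nInput + iH, drop = FALSE]

  for (t in rev(seq_len(L))) {
    s <- cache[[t]]
    dgo <- dh * s$tc
    dc <- dc + dh * s$go * (1 - s$tc^2)
    dgi <- dc * s$gg
    dgg <- dc * s$gi
    dgf <- dc * s$cPrev
    dcPrev <- dc * s$gf
    dzi <- dgi * s$gi * (1 - s$gi)
    dzf <- dgf * s$gf * (1 - s$gf)
    dzg <- dgg * (1 - s$gg^2)
    dzo <- dgo * s$go * (1 - s$go)
    dz <- cbind(dzi, dzf, dzg, dzo) # B x 4H, gate order i,f,g,o
    dW <- dW + t(dz) %*% cbind(s$xt, s$hPrev)
    db <- db + colSums(dz)
    dh <- dz %*% params$W[, params$nInput + iH, drop = FALSE]
    dc <- dcPrev
  }
  list(W = dW, b = db, Wy = dWy, by = dby)
}

# Adam step; state holds first/second moments and the step counter.
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in c("W", "b", "Wy", "by")) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mHat <- state$m[[nm]] / (1 - beta1^state$t)
    vHat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mHat / (sqrt(vHat) + eps)
  }
  list(params = params, state = state)
}

adamInit <- function(params) {
  zero <- lapply(params[c("W", "b", "Wy", "by")], function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}

# Predicted class indices (1-based) for an (n, L, C) array.
lstmPredict <- function(params, X, chunk = 512L) {
  n <- dim(X)[1]
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    Xi <- X[idx, , , drop = FALSE]
    logits <- lstmForward(params, Xi)$logits
    out[idx] <- max.col(logits, ties.method = "first")
  }
  out
}
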