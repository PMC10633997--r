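# Compact dense-network engine for the descriptor-based property models.
# tanh hidden layers, inverted dropout, Adam, minibatches, early stopping on
# a validation set, and three output heads:
#   point      - 1 output, squared-error loss
#   mve        - 2 outputs (mu, s); sigma^2 = softplus(s) + floor, Gaussian NLL
#   evidential - 4 outputs -> NIG (gamma, upsilon, alpha, beta) via softplus
#                maps (alpha = 1 + softplus to keep moments finite), trained
#                with the marginal Student-t NLL plus an evidence regularizer
#                lambda * |y - gamma| * (2 upsilon + alpha).
# All arithmetic is plain BLAS-backed matrix algebra; gradients are analytic.

headDim <- function(head) switch(head, point = 1L, mve = 2L, evidential = 4L,
                                 stop("unknown head: ", head, call. = FALSE))

mlpInit <- function(p, hidden, nOut, seed) {
  dims <- c(p, hidden, nOut)
  withSeed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(1 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    list(W = W, b = b, dims = dims)
  })
}

# Forward pass. dropMasks: NULL (no dropout) or list of n x d_l binary masks
# already scaled by 1/(1-rate) (inverted dropout). Returns activations too
# when cache = TRUE (needed for backprop and last-layer extraction).
mlpForward <- function(net, X, dropMasks = NULL, cache = FALSE) {
  L <- length(net$W)
  A <- X
  acts <- if (cache) vector("list", L + 1L)
  if (cache) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]] + matrix(net$b[[l]], nrow(A), length(net$b[[l]]),
                                   byrow = TRUE)
    A <- if (l < L) tanh(Z) else Z
    if (l < L && !is.null(dropMasks)) A <- A * dropMasks[[l]]
    if (cache) acts[[l + 1L]] <- A
  }
  if (cache) list(out = A, acts = acts) else A
}

makeDropMasks <- function(net, n, rate) {
  if (rate <= 0) return(NULL)
  L <- length(net$W)
  lapply(seq_len(L - 1L), function(l) {
    d <- ncol(net$W[[l]])
    matrix((runif(n * d) >= rate) / (1 - rate), n, d)
  })
}

# Backprop given dOut = dLoss/dOut (n x K, already averaged over n).
mlpBackward <- function(net, fw, dOut, dropMasks = NULL) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- dOut
  for (l in rev(seq_len(L))) {
    A_prev <- fw$acts[[l]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, net$W[[l]])
      if (!is.null(dropMasks)) dA <- dA * dropMasks[[l - 1L]]
      dZ <- dA * (1 - fw$acts[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

SIGMA2_FLOOR <- 1e-6
EVID_FLOOR <- 1e-6

# Head-specific loss and gradient wrt the raw network outputs.
# Returns list(loss = scalar mean loss, dOut = n x K gradient of the MEAN
# loss wrt raw outputs).
headLoss <- function(head, out, y, lambda = 0.01) {
  n <- length(y)
  if (head == "point") {
    r <- drop(out) - y
    list(loss = mean(r^2) / 2, dOut = matrix(r / n, ncol = 1L))
  } else if (head == "mve") {
    mu <- out[, 1L]; s <- out[, 2L]
    sig2 <- softplus(s) + SIGMA2_FLOOR
    r <- y - mu
    loss <- mean(0.5 * log(2 * pi) + 0.5 * log(sig2) + r^2 / (2 * sig2))
    dmu <- -r / sig2
    dsig2 <- 0.5 / sig2 - r^2 / (2 * sig2^2)
    list(loss = loss,
         dOut = cbind(dmu, dsig2 * sigmoid(s)) / n)
  } else if (head == "evidential") {
    gamma <- out[, 1L]
    ups <- softplus(out[, 2L]) + EVID_FLOOR
    alpha <- 1 + softplus(out[, 3L]) + EVID_FLOOR
    beta <- softplus(out[, 4L]) + EVID_FLOOR
    e <- y - gamma
    Om <- 2 * beta * (1 + ups)
    A <- e^2 * ups + Om
    nll <- 0.5 * (log(pi) - log(ups)) - alpha * log(Om) +
      (alpha + 0.5) * log(A) + lgamma(alpha) - lgamma(alpha + 0.5)
    reg <- lambda * abs(e) * (2 * ups + alpha)
    dgamma <- (alpha + 0.5) * (-2 * e * ups) / A - lambda * sign(e) * (2 * ups + alpha)
    dups <- -0.5 / ups - alpha * (2 * beta) / Om +
      (alpha + 0.5) * (e^2 + 2 * beta) / A + 2 * lambda * abs(e)
    dalpha <- -log(Om) + log(A) + digamma(alpha) - digamma(alpha + 0.5) +
      lambda * abs(e)
    dbeta <- -alpha / beta + (alpha + 0.5) * 2 * (1 + ups) / A
    list(loss = mean(nll + reg),
         dOut = cbind(dgamma,
                      dups * sigmoid(out[, 2L]),
                      dalpha * sigmoid(out[, 3L]),
                      dbeta * sigmoid(out[, 4L])) / n)
  } else stop("unknown head: ", head, call. = FALSE)
}

adamInit <- function(net) {
  list(m = lapply(net$W, function(w) w * 0), v = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$m[[l]] <- beta1 * state$m[[l]] + (1 - beta1) * grads$W[[l]]
    state$v[[l]] <- beta2 * state$v[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$m[[l]] / c1) / (sqrt(state$v[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# Flatten / restore all weights for use with stats::optim.
netFlatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), net$b), use.names = FALSE)
}
netRestore <- function(net, par) {
  off <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- par[off + seq_len(k)]; off <- off + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]] <- par[off + seq_len(k)]; off <- off + k
  }
  net
}

# Deterministic full-batch L-BFGS refinement of a trained net (no dropout).
# Adam finds the basin; this polishes to a much lower loss, which matters
# for near-noiseless targets where minibatch noise sets the error floor.
mlpPolish <- function(net, X, y, head, lambda = 0.01, maxit = 200L) {
  fn <- function(par) {
    headLoss(head, mlpForward(netRestore(net, par), X), y, lambda)$loss
  }
  gr <- function(par) {
    nt <- netRestore(net, par)
    fw <- mlpForward(nt, X, cache = TRUE)
    hl <- headLoss(head, fw$out, y, lambda)
    g <- mlpBackward(nt, fw, hl$dOut)
    unlist(c(lapply(g$W, as.numeric), g$b), use.names = FALSE)
  }
  res <- stats::optim(netFlatten(net), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  netRestore(net, res$par)
}

# Core training loop on already-standardized matrices.
mlpTrain <- function(Xtr, ytr, Xva, yva, head, hidden, dropoutRate, maxEpochs,
                     learningRate, batchSize, patience, seed, lambda = 0.01,
                     lrDecay = 1) {
  net <- mlpInit(ncol(Xtr), hidden, headDim(head), derivedSeed(seed, "model-init"))
  state <- adamInit(net)
  n <- nrow(Xtr)
  best <- list(net = net, loss = Inf, epoch = 0L)
  wait <- 0L
  withSeed(derivedSeed(seed, "model-train"), {
    for (epoch in seq_len(maxEpochs)) {
      lrEpoch <- learningRate * lrDecay^(epoch - 1L)
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        masks <- makeDropMasks(net, length(idx), dropoutRate)
        fw <- mlpForward(net, Xtr[idx, , drop = FALSE], masks, cache = TRUE)
        hl <- headLoss(head, fw$out, ytr[idx], lambda)
        if (!is.finite(hl$loss))
          stop("training divergence: non-finite loss", call. = FALSE)
        grads <- mlpBackward(net, fw, hl$dOut, masks)
        upd <- adamStep(net, grads, state, lrEpoch)
        net <- upd$net; state <- upd$state
      }
      vloss <- headLoss(head, mlpForward(net, Xva), yva, lambda)$loss
      if (!is.finite(vloss))
        stop("training divergence: non-finite validation loss", call. = FALSE)
      if (vloss < best$loss - 1e-9) {
        best <- list(net = net, loss = vloss, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (patience > 0L && wait >= patience) break
      }
    }
  })
  best
}
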