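#' Specification of the descriptor-based feedforward property model
#'
#' Architecture and optimisation settings for the fully connected network
#' used by the neural UQ estimators. Defaults are sized for desk-scale
#' synthetic datasets (a few thousand molecules, tens of descriptors).
#'
#' @param hiddenSizes integer vector of hidden-layer widths (>= 1 layer).
#' @param dropoutRate dropout probability in \[0,1) applied to hidden
#'   activations during training (and at inference for MC dropout).
#' @param maxEpochs maximum training epochs.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (0 disables early stopping).
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout masks.
#' @param lrDecay multiplicative per-epoch learning-rate decay in (0,1\];
#'   1 keeps the step size constant.
#' @param polishIters full-batch L-BFGS refinement iterations run after the
#'   stochastic phase (deterministic, no dropout; only used when
#'   `dropoutRate == 0`). The polished weights are kept only if they do not
#'   worsen the validation loss. 0 disables.
#' @return a `RegressorSpec` list.
#' @export
regressorSpec <- function(hiddenSizes = c(128, 64), dropoutRate = 0.2,
                          maxEpochs = 200, learningRate = 1e-3,
                          batchSize = 64, earlyStopPatience = 20, seed = 1,
                          lrDecay = 1, polishIters = 0) {
  if (length(hiddenSizes) < 1L || any(hiddenSizes < 1))
    stop("configuration error: at least one positive hidden layer", call. = FALSE)
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("configuration error: dropoutRate must be in [0,1)", call. = FALSE)
  if (maxEpochs < 1 || learningRate <= 0 || batchSize < 1 || earlyStopPatience < 0)
    stop("configuration error: invalid optimisation settings", call. = FALSE)
  if (lrDecay <= 0 || lrDecay > 1)
    stop("configuration error: lrDecay must lie in (0,1]", call. = FALSE)
  structure(list(hiddenSizes = as.integer(hiddenSizes),
                 dropoutRate = dropoutRate, maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, batchSize = as.integer(batchSize),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 seed = as.integer(seed), lrDecay = lrDecay,
                 polishIters = as.integer(polishIters)),
            class = "RegressorSpec")
}

#' Train the feedforward property model
#'
#' Standardizes descriptors and target with training-set statistics only,
#' then trains a tanh network with the requested output head:
#' `"point"` (squared error), `"mve"` (mean and variance under a Gaussian
#' negative log-likelihood) or `"evidential"` (the four parameters of a
#' Normal-Inverse-Gamma evidential distribution, trained with the marginal
#' Student-t negative log-likelihood plus an evidence regularizer).
#' Training is deterministic given the spec seed; early stopping monitors
#' the validation loss and the best-validation weights are kept.
#'
#' @param spec a [regressorSpec()].
#' @param train training [MoleculeSet].
#' @param val validation [MoleculeSet]; if NULL, a seeded 10% split of
#'   `train` is carved out.
#' @param head one of `"point"`, `"mve"`, `"evidential"`.
#' @param lambda evidence-regularizer weight (evidential head only).
#' @return an object of class `mlpModel` with a stored scaler; see
#'   [predictRegressor()].
#' @export
trainRegressor <- function(spec, train, val = NULL,
                           head = c("point", "mve", "evidential"),
                           lambda = 0.01) {
  head <- match.arg(head)
  stopifnot(inherits(spec, "RegressorSpec"), is(train, "MoleculeSet"))
  if (is.null(val)) {
    n <- nMolecules(train)
    vIdx <- withSeed(derivedSeed(spec$seed, "val-split"),
                     sample.int(n, max(2L, round(0.1 * n))))
    val <- train[vIdx]
    train <- train[-vIdx]
  }
  if (ncol(descriptors(train)) != ncol(descriptors(val)))
    stop("input error: train and val feature dimensions differ", call. = FALSE)
  scaler <- fitScaler(descriptors(train))
  yMean <- mean(targets(train)); ySd <- sd(targets(train))
  if (!is.finite(ySd) || ySd == 0) ySd <- 1
  Xtr <- applyScaler(scaler, descriptors(train))
  Xva <- applyScaler(scaler, descriptors(val))
  ytrS <- (targets(train) - yMean) / ySd
  yvaS <- (targets(val) - yMean) / ySd
  fit <- mlpTrain(Xtr, ytrS, Xva, yvaS,
                  head, spec$hiddenSizes, spec$dropoutRate, spec$maxEpochs,
                  spec$learningRate, spec$batchSize, spec$earlyStopPatience,
                  spec$seed, lambda, spec$lrDecay)
  if (spec$polishIters > 0L && spec$dropoutRate == 0) {
    polished <- mlpPolish(fit$net, Xtr, ytrS, head, lambda, spec$polishIters)
    vloss <- headLoss(head, mlpForward(polished, Xva), yvaS, lambda)$loss
    if (is.finite(vloss) && vloss <= fit$loss) {
      fit$net <- polished
      fit$loss <- vloss
    }
  }
  structure(list(net = fit$net, head = head, spec = spec, scaler = scaler,
                 yMean = yMean, ySd = ySd, bestEpoch = fit$epoch,
                 valLoss = fit$loss, lambda = lambda),
            class = "mlpModel")
}

# Raw head outputs on the standardized scale (dropout off unless masks given).
modelRawOut <- function(model, X, dropMasks = NULL) {
  mlpForward(model$net, applyScaler(model$scaler, X), dropMasks)
}

#' Predictions from a trained feedforward model
#'
#' For `head = "point"` returns `list(mean)`. For `"mve"` returns
#' `list(mean, sigma2)` on the original target scale. For `"evidential"`
#' returns `list(mean, gamma, upsilon, alpha, beta)` with `gamma` on the
#' original scale and `beta` rescaled so the Normal-Inverse-Gamma moments
#' are in squared target units; `upsilon > 0` and `alpha > 1` always hold.
#'
#' @param model an `mlpModel` from [trainRegressor()].
#' @param X descriptor matrix (raw scale).
#' @return a list of per-row predictions.
#' @export
predictRegressor <- function(model, X) {
  stopifnot(inherits(model, "mlpModel"))
  out <- modelRawOut(model, X)
  if (model$head == "point") {
    list(mean = drop(out) * model$ySd + model$yMean)
  } else if (model$head == "mve") {
    mu <- out[, 1L] * model$ySd + model$yMean
    sig2 <- (softplus(out[, 2L]) + SIGMA2_FLOOR) * model$ySd^2
    list(mean = mu, sigma2 = sig2)
  } else {
    gamma <- out[, 1L] * model$ySd + model$yMean
    ups <- softplus(out[, 2L]) + EVID_FLOOR
    alpha <- 1 + softplus(out[, 3L]) + EVID_FLOOR
    beta <- (softplus(out[, 4L]) + EVID_FLOOR) * model$ySd^2
    list(mean = gamma, gamma = gamma, upsilon = ups, alpha = alpha, beta = beta)
  }
}

#' Extract last-hidden-layer representations
#'
#' Deterministic (dropout disabled) activations of the final hidden layer,
#' the learned molecular representation consumed by the union approach.
#'
#' @param model an `mlpModel`.
#' @param X descriptor matrix (raw scale).
#' @return an `nrow(X) x H` matrix, H the final hidden width.
#' @export
extractLastLayer <- function(model, X) {
  if (!inherits(model, "mlpModel"))
    stop("unsupported model: expected a feedforward mlpModel", call. = FALSE)
  fw <- mlpForward(model$net, applyScaler(model$scaler, X), cache = TRUE)
  fw$acts[[length(fw$acts) - 1L]]
}

#' Fit a gradient-boosted tree model at a given quantile
#'
#' Gradient boosting with the pinball (quantile) loss, the baseline UQ
#' model: trained at the 10% and 90% quantiles its prediction interval
#' yields an uncertainty via half the interquantile range.
#'
#' @param train training [MoleculeSet] (or a list with elements `X`, `y`).
#' @param quantile target quantile strictly inside (0,1); `NA` fits the
#'   conditional mean (squared-error loss) instead.
#' @param seed integer seed.
#' @param nrounds,maxDepth,eta boosting rounds, tree depth, learning rate.
#'   The defaults are deliberately conservative: pinball-loss boosting
#'   overfits quickly, and overfit quantile models produce collapsed
#'   prediction intervals whose held-out coverage falls well short of the
#'   nominal level.
#' @param minChildWeight,subsample additional regularisation passed to the
#'   booster.
#' @param X,y alternative raw-matrix interface overriding `train`.
#' @return a `gbmModel` wrapping an xgboost booster.
#' @export
fitQuantileGbm <- function(train = NULL, quantile = 0.5, seed = 1,
                           nrounds = 100, maxDepth = 2, eta = 0.1,
                           minChildWeight = 40, subsample = 0.6,
                           X = NULL, y = NULL) {
  if (is.null(X)) { X <- descriptors(train); y <- targets(train) }
  if (!is.na(quantile) && (quantile <= 0 || quantile >= 1))
    stop("configuration error: quantile must lie strictly in (0,1)", call. = FALSE)
  params <- list(max_depth = maxDepth, eta = eta, nthread = 1,
                 min_child_weight = minChildWeight, subsample = subsample,
                 seed = as.integer(seed))
  if (is.na(quantile)) {
    params$objective <- "reg:squarederror"
  } else {
    params$objective <- "reg:quantileerror"
    params$quantile_alpha <- quantile
  }
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, quantile = quantile, seed = seed),
            class = "gbmModel")
}

#' @rdname fitQuantileGbm
#' @param model a `gbmModel`.
#' @export
predictGbm <- function(model, X) {
  stopifnot(inherits(model, "gbmModel"))
  predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}
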