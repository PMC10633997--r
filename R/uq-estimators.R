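newUQ <- function(ids, mean, sigma, calibrated, method) {
  new("UQEstimate", ids = as.character(ids), mean = as.numeric(mean),
      sigma = as.numeric(sigma), calibrated = calibrated, method = method)
}

#' Uncertainty from quantile-GBM prediction intervals
#'
#' Half the range between the upper (90%) and lower (10%) quantile
#' predictions. Crossed quantiles (upper below lower) are clipped to zero
#' uncertainty with a warning, since the half-range presumes ordered
#' quantiles.
#'
#' @param predLo,predHi lower/upper quantile predictions.
#' @param meanPred mean predictions (the model's property estimate).
#' @param ids molecule identifiers.
#' @return a calibrated [UQEstimate] with method `"gbm"`.
#' @examples
#' gbmQuantileUQ(1, 3, 2, "a")  # sigma 1
#' @export
gbmQuantileUQ <- function(predLo, predHi, meanPred, ids = NULL) {
  if (length(predLo) != length(predHi) || length(predHi) != length(meanPred))
    stop("input error: prediction vectors must be aligned", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(meanPred))
  width <- (predHi - predLo) / 2
  if (any(width < 0)) {
    warning(sum(width < 0), " crossed quantile pair(s) clipped to zero uncertainty")
    width <- pmax(width, 0)
  }
  newUQ(ids, meanPred, width, TRUE, "gbm")
}

#' Aggregate member predictions into an ensemble uncertainty estimate
#'
#' @param predMatrix n x M matrix, one column per ensemble member.
#' @param ids molecule identifiers.
#' @param method tag for the resulting estimate.
#' @return [UQEstimate] with mean = row mean, sigma = population
#'   (divide-by-M) standard deviation across members.
#' @export
aggregateEnsemble <- function(predMatrix, ids = NULL, method = "ensemble") {
  if (ncol(predMatrix) < 2L)
    stop("configuration error: an ensemble needs at least 2 members", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(predMatrix)))
  newUQ(ids, rowMeans(predMatrix), rowPopSd(predMatrix), TRUE, method)
}

#' Deep-ensemble uncertainty
#'
#' Trains `M` structurally identical point-head networks differing only in
#' seed (weight initialisation, shuffling, dropout masks) and reports the
#' spread of their predictions as the uncertainty.
#'
#' @param spec base [regressorSpec()]; member seeds are derived from it.
#' @param train,val training/validation [MoleculeSet]s (`val` may be NULL).
#' @param Xquery descriptor matrix to predict on.
#' @param M ensemble size (>= 2).
#' @param ids molecule identifiers for the query rows.
#' @return a calibrated [UQEstimate] with method `"ensemble"`.
#' @export
ensembleUQ <- function(spec, train, val = NULL, Xquery, M = 5, ids = NULL) {
  if (M < 2) stop("configuration error: M must be >= 2", call. = FALSE)
  preds <- vapply(seq_len(M), function(m) {
    s <- spec
    s$seed <- derivedSeed(spec$seed, paste0("ensemble-member-", m))
    predictRegressor(trainRegressor(s, train, val, head = "point"), Xquery)$mean
  }, numeric(nrow(Xquery)))
  aggregateEnsemble(preds, ids, "ensemble")
}

#' Monte Carlo dropout uncertainty
#'
#' Runs `T` stochastic forward passes with dropout masks active at
#' inference and reports the mean and population standard deviation across
#' passes. Deterministic given `seed`.
#'
#' @param model an `mlpModel` trained with `dropoutRate > 0` (a model
#'   without dropout layers is rejected).
#' @param Xquery descriptor matrix.
#' @param T number of stochastic passes (>= 2).
#' @param seed pass-mask seed.
#' @param ids molecule identifiers.
#' @return a calibrated [UQEstimate] with method `"mcdo"`.
#' @export
mcdoUQ <- function(model, Xquery, T = 30, seed = 1, ids = NULL) {
  stopifnot(inherits(model, "mlpModel"))
  if (model$head != "point" && model$head != "mve")
    stop("unsupported model: MC dropout uses the mean prediction head", call. = FALSE)
  if (T < 2) stop("configuration error: T must be >= 2", call. = FALSE)
  # dropoutRate 0 is permitted and collapses to deterministic passes (sigma 0)
  rate <- model$spec$dropoutRate
  Xs <- applyScaler(model$scaler, Xquery)
  preds <- withSeed(derivedSeed(seed, "mcdo-pass"), {
    vapply(seq_len(T), function(t) {
      masks <- makeDropMasks(model$net, nrow(Xs), rate)
      out <- mlpForward(model$net, Xs, masks)
      out[, 1L] * model$ySd + model$yMean
    }, numeric(nrow(Xs)))
  })
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xquery)))
  newUQ(ids, rowMeans(preds), rowPopSd(preds), TRUE, "mcdo")
}

#' Gaussian negative log-likelihood of the mean-variance head
#'
#' `0.5 log(2 pi) + 0.5 log(sigma2) + (y - mu)^2 / (2 sigma2)`.
#'
#' @param y observed target, `mu` predicted mean, `sigma2` predicted
#'   variance (> 0). Vectorized.
#' @param mu,sigma2 see above.
#' @return per-observation loss values.
#' @export
mveNllLoss <- function(y, mu, sigma2) {
  if (any(sigma2 <= 0))
    stop("domain error: sigma2 must be positive", call. = FALSE)
  0.5 * log(2 * pi) + 0.5 * log(sigma2) + (y - mu)^2 / (2 * sigma2)
}

#' Mean-variance estimation uncertainty
#'
#' The predicted standard deviation `sqrt(sigma2(x))` of a network trained
#' with the Gaussian negative log-likelihood is reported as the
#' uncertainty, on the error scale of the target.
#'
#' @param model an `mlpModel` with `head = "mve"`.
#' @param Xquery descriptor matrix.
#' @param ids molecule identifiers.
#' @return a calibrated [UQEstimate] with method `"mve"`.
#' @export
mveUQ <- function(model, Xquery, ids = NULL) {
  if (!inherits(model, "mlpModel") || model$head != "mve")
    stop("unsupported model: mveUQ needs an mve-head model", call. = FALSE)
  pr <- predictRegressor(model, Xquery)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xquery)))
  newUQ(ids, pr$mean, sqrt(pr$sigma2), TRUE, "mve")
}

#' Log density of the Normal-Inverse-Gamma evidential distribution
#'
#' Evaluates the joint NIG density over (mu, sigma2):
#' `beta^alpha sqrt(upsilon) / (Gamma(alpha) sqrt(2 pi sigma2)) *
#'  (1/sigma2)^(alpha+1) exp(-(2 beta + upsilon (gamma - mu)^2) / (2 sigma2))`
#' on the log scale.
#'
#' @param mu,sigma2 evaluation point (`sigma2 > 0`). Vectorized.
#' @param gamma,upsilon,alpha,beta NIG parameters; requires `upsilon > 0`,
#'   `alpha > 1`, `beta > 0` (the finite-moment region).
#' @return log density values.
#' @export
nigLogDensity <- function(mu, sigma2, gamma, upsilon, alpha, beta) {
  if (any(sigma2 <= 0)) stop("domain error: sigma2 must be > 0", call. = FALSE)
  if (any(upsilon <= 0) || any(alpha <= 1) || any(beta <= 0))
    stop("domain error: need upsilon > 0, alpha > 1, beta > 0", call. = FALSE)
  alpha * log(beta) + 0.5 * log(upsilon) - lgamma(alpha) -
    0.5 * log(2 * pi * sigma2) - (alpha + 1) * log(sigma2) -
    (2 * beta + upsilon * (gamma - mu)^2) / (2 * sigma2)
}

#' Moments of the Normal-Inverse-Gamma distribution
#'
#' Predicted mean `E[mu] = gamma`, aleatoric variance
#' `E[sigma2] = beta / (alpha - 1)` and epistemic variance
#' `Var[mu] = beta / (upsilon (alpha - 1))`.
#'
#' @param gamma,upsilon,alpha,beta NIG parameters (vectorized);
#'   `alpha > 1` and `upsilon > 0` required for finite moments.
#' @return list with `predMean`, `aleatoric`, `epistemic`.
#' @examples
#' nigMoments(2, 1, 3, 4)  # mean 2, aleatoric 2, epistemic 2
#' @export
nigMoments <- function(gamma, upsilon, alpha, beta) {
  if (any(alpha <= 1))
    stop("domain error: alpha must exceed 1 (infinite moments)", call. = FALSE)
  if (any(upsilon <= 0))
    stop("domain error: upsilon must be positive", call. = FALSE)
  list(predMean = gamma, aleatoric = beta / (alpha - 1),
       epistemic = beta / (upsilon * (alpha - 1)))
}

#' Evidential regression uncertainty
#'
#' Reports the square root of the selected variance component of the
#' predicted Normal-Inverse-Gamma distribution: `"epistemic"` (Var\[mu\],
#' the default), `"aleatoric"` (E\[sigma2\]) or `"total"` (their sum).
#'
#' @param model an `mlpModel` with `head = "evidential"`.
#' @param Xquery descriptor matrix.
#' @param report which variance component to report.
#' @param ids molecule identifiers.
#' @return a calibrated [UQEstimate] with method `"evidential"`.
#' @export
evidentialUQ <- function(model, Xquery,
                         report = c("epistemic", "aleatoric", "total"),
                         ids = NULL) {
  report <- match.arg(report)
  if (!inherits(model, "mlpModel") || model$head != "evidential")
    stop("unsupported model: evidentialUQ needs an evidential-head model",
         call. = FALSE)
  pr <- predictRegressor(model, Xquery)
  mom <- nigMoments(pr$gamma, pr$upsilon, pr$alpha, pr$beta)
  v <- switch(report, epistemic = mom$epistemic, aleatoric = mom$aleatoric,
              total = mom$aleatoric + mom$epistemic)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xquery)))
  newUQ(ids, mom$predMean, sqrt(v), TRUE, "evidential")
}

#' Union uncertainty: neural representation + quantile GBM
#'
#' Extracts last-hidden-layer features from a trained feedforward model for
#' both training and query molecules, fits quantile gradient-boosted trees
#' on (features, y) at the lower/upper quantiles, and converts the interval
#' to an uncertainty via [gbmQuantileUQ()]. The neural model's own
#' prediction is kept as the property estimate.
#'
#' @param model a trained `mlpModel`.
#' @param train training [MoleculeSet].
#' @param Xquery descriptor matrix for query molecules.
#' @param quantiles lower/upper quantile pair.
#' @param seed GBM seed.
#' @param ids molecule identifiers.
#' @return a calibrated [UQEstimate] with method `"union"`.
#' @export
unionUQ <- function(model, train, Xquery, quantiles = c(0.1, 0.9), seed = 1,
                    ids = NULL) {
  H_train <- extractLastLayer(model, descriptors(train))
  H_query <- extractLastLayer(model, Xquery)
  lo <- fitQuantileGbm(quantile = quantiles[1], seed = seed,
                       X = H_train, y = targets(train))
  hi <- fitQuantileGbm(quantile = quantiles[2], seed = seed,
                       X = H_train, y = targets(train))
  meanPred <- predictRegressor(model, Xquery)$mean
  est <- gbmQuantileUQ(predictGbm(lo, H_query), predictGbm(hi, H_query),
                       meanPred, ids)
  est@method <- "union"
  est
}

#' k-nearest-neighbour density uncertainty
#'
#' The mean cosine distance (1 - cosine similarity) from each query
#' molecule to its `k` nearest training molecules in a shared
#' representation space (descriptors for the fingerprint analogue,
#' embeddings for the embedding analogue). A purely dataset-dependent,
#' relative score: `calibrated` is FALSE and ENCE is not applicable.
#'
#' @param trainReps,queryReps representation matrices in the same space.
#' @param k number of neighbours (default 3).
#' @param ids molecule identifiers.
#' @param meanPred optional base-model predictions to carry along.
#' @param method tag (`"knn_fp"` or `"knn_eb"` by convention).
#' @return an uncalibrated [UQEstimate].
#' @export
knnDensityUQ <- function(trainReps, queryReps, k = 3, ids = NULL,
                         meanPred = NULL, method = "knn") {
  if (nrow(trainReps) < k)
    stop("configuration error: fewer than k training rows", call. = FALSE)
  sim <- cosineCross(queryReps, trainReps)
  d <- 1 - sim
  sigma <- apply(d, 1L, function(r) mean(sort(r, partial = k)[seq_len(k)]))
  sigma <- pmax(sigma, 0)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(queryReps)))
  if (is.null(meanPred)) meanPred <- rep(NA_real_, nrow(queryReps))
  newUQ(ids, meanPred, sigma, FALSE, method)
}

#' Consensus of several calibrated uncertainty estimates
#'
#' Elementwise arithmetic mean of the member means and of the member
#' sigmas (the combination used with the quantile-GBM, MC-dropout and MVE
#' estimates).
#'
#' @param estimates list of >= 2 aligned calibrated [UQEstimate]s.
#' @return a calibrated [UQEstimate] with method `"consensus"`.
#' @export
consensusUQ <- function(estimates) {
  if (length(estimates) < 2L)
    stop("configuration error: consensus needs >= 2 estimates", call. = FALSE)
  ids <- molIds(estimates[[1L]])
  for (e in estimates) {
    if (!identical(molIds(e), ids))
      stop("input error: estimates have misaligned molecule ids", call. = FALSE)
    if (!isCalibrated(e))
      stop("input error: consensus requires calibrated estimates", call. = FALSE)
  }
  m <- rowMeans(vapply(estimates, uqMean, numeric(length(ids))))
  s <- rowMeans(vapply(estimates, uqSigma, numeric(length(ids))))
  newUQ(ids, m, s, TRUE, "consensus")
}
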