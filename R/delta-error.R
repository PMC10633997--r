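# Leave-bin-out study driver: trains a full model and one bin-removed model
# per (component, bin) scenario, records removed-bin test RMSE and mean UQ
# under both, and feeds rhoDeltaError.

#' Seeded random train/validation/test split
#'
#' @param n number of molecules.
#' @param fractions length-3 vector (train, val, test) summing to 1.
#' @param seed split seed.
#' @return list with integer `trainIdx`, `valIdx`, `testIdx`.
#' @export
randomSplit <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  withSeed(derivedSeed(seed, "split"), {
    ord <- sample.int(n)
    nTr <- round(fractions[1] * n)
    nVa <- round(fractions[2] * n)
    list(trainIdx = sort(ord[seq_len(nTr)]),
         valIdx = sort(ord[nTr + seq_len(nVa)]),
         testIdx = sort(ord[(nTr + nVa + 1L):n]))
  })
}

# Model-family adapter: fits on a training MoleculeSet and predicts means.
# "gbm" is the fast default for study drivers; "mlp" uses the feedforward
# network.
fitMeanModel <- function(family, train, seed, gbmRounds = 150, gbmDepth = 4,
                         gbmEta = 0.1, mlpSpec = NULL) {
  if (family == "gbm") {
    m <- fitQuantileGbm(train, quantile = NA, seed = seed,
                        nrounds = gbmRounds, maxDepth = gbmDepth, eta = gbmEta,
                        minChildWeight = 5, subsample = 0.8)
    list(predict = function(X) predictGbm(m, X), model = m)
  } else if (family == "mlp") {
    spec <- if (is.null(mlpSpec)) regressorSpec(hiddenSizes = c(64, 32),
                                                dropoutRate = 0,
                                                maxEpochs = 150, seed = seed)
            else { s <- mlpSpec; s$seed <- seed; s }
    m <- trainRegressor(spec, train, head = "point")
    list(predict = function(X) predictRegressor(m, X)$mean, model = m)
  } else stop("unknown model family: ", family, call. = FALSE)
}

#' Run the leave-bin-out delta-error study
#'
#' For each (component, bin) scenario: train the model on the full training
#' set and on the bin-removed training set, and record the RMSE and mean
#' uncertainty over the removed bin's test molecules under both. The
#' uncertainty comes from k-nearest-neighbour density against the
#' respective training set (descriptor space by default), the estimator
#' whose dataset dependence this study isolates.
#'
#' @param data a [MoleculeSet].
#' @param nComponents,nBins PCA components and bins per component.
#' @param modelFamily `"gbm"` (fast default) or `"mlp"`.
#' @param uqSpace `"descriptors"` or `"embeddings"` for the density UQ.
#' @param k density neighbours.
#' @param seed split/model seed.
#' @param fractions train/val/test fractions.
#' @return list with `rho`, the per-scenario `table`, and the full split.
#' @export
runDeltaErrorStudy <- function(data, nComponents = 3, nBins = 5,
                               modelFamily = "gbm",
                               uqSpace = c("descriptors", "embeddings"),
                               k = 3, seed = 1,
                               fractions = c(0.7, 0.1, 0.2)) {
  uqSpace <- match.arg(uqSpace)
  reps <- if (uqSpace == "descriptors") descriptors(data) else embeddings(data)
  n <- nMolecules(data)
  split <- randomSplit(n, fractions, seed)
  assignments <- pcaTopBins(descriptors(data), nComponents, nBins)

  Xtest <- descriptors(data)[split$testIdx, , drop = FALSE]
  yTest <- targets(data)[split$testIdx]
  trainFull <- data[split$trainIdx]
  fullFit <- fitMeanModel(modelFamily, trainFull, derivedSeed(seed, "full-model"))
  predFull <- fullFit$predict(Xtest)
  uqFullAll <- uqSigma(knnDensityUQ(reps[split$trainIdx, , drop = FALSE],
                                    reps[split$testIdx, , drop = FALSE], k))

  rows <- list()
  for (a in assignments) {
    for (b in seq_len(nBins)) {
      lbo <- leaveBinOut(split, a, b)
      testInBin <- which(a@binOf[split$testIdx] == b)
      if (length(testInBin) < 2L) next
      trainRed <- data[lbo@trainIdx]
      redFit <- fitMeanModel(modelFamily, trainRed,
                             derivedSeed(seed, sprintf("lbo-%d-%d", a@pcIndex, b)))
      predRed <- redFit$predict(Xtest)
      uqRedAll <- uqSigma(knnDensityUQ(reps[lbo@trainIdx, , drop = FALSE],
                                       reps[split$testIdx, , drop = FALSE], k))
      rows[[length(rows) + 1L]] <- data.frame(
        pcIndex = a@pcIndex, binIndex = b,
        rmseFull = rmse(yTest[testInBin], predFull[testInBin]),
        rmseRemoved = rmse(yTest[testInBin], predRed[testInBin]),
        uqFull = mean(uqFullAll[testInBin]),
        uqRemoved = mean(uqRedAll[testInBin]))
    }
  }
  scen <- do.call(rbind, rows)
  res <- rhoDeltaError(scen)
  res$split <- split
  res
}
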