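#' Configuration for an end-to-end uncertainty-quantification study
#'
#' @param dataConfig a [syntheticConfig()] (or NULL with `dataPath` set).
#' @param dataPath CSV path of a stored [MoleculeSet] (overrides
#'   `dataConfig` for data loading).
#' @param uqMethods character vector of estimator names; valid names are
#'   `"gbm"`, `"ensemble"`, `"mcdo"`, `"mve"`, `"evidential"`, `"union"`,
#'   `"knn_fp"`, `"knn_eb"`, `"consensus"`.
#' @param includeDeltaError run the leave-bin-out delta-error study for
#'   each method (the expensive metric); with `reduced = TRUE` only the
#'   density methods get it.
#' @param reduced desk-scale settings: smaller networks, 1 PCA component
#'   for the delta-error study, reduced AL grid.
#' @param alFractions,alNAdds,alReps active-learning grid settings.
#' @param outDir output directory (created if missing); NULL disables
#'   caching and report writing.
#' @param seed global seed.
#' @return a `StudyConfig` list.
#' @export
studyConfig <- function(dataConfig = syntheticConfig(), dataPath = NULL,
                        uqMethods = c("gbm", "mve", "knn_fp", "knn_eb"),
                        includeDeltaError = FALSE, reduced = TRUE,
                        alFractions = 0.1, alNAdds = c(50, 100), alReps = 5,
                        outDir = NULL, seed = 1) {
  valid <- c("gbm", "ensemble", "mcdo", "mve", "evidential", "union",
             "knn_fp", "knn_eb", "consensus")
  bad <- setdiff(uqMethods, valid)
  if (length(bad))
    stop("configuration error: unknown method(s) ",
         paste(bad, collapse = ", "), "; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  list(dataConfig = dataConfig, dataPath = dataPath, uqMethods = uqMethods,
       includeDeltaError = includeDeltaError, reduced = reduced,
       alFractions = alFractions, alNAdds = alNAdds, alReps = alReps,
       outDir = outDir, seed = as.integer(seed))
}

studyData <- function(study) {
  if (!is.null(study$dataPath)) readMoleculeSet(study$dataPath)
  else generateDataset(study$dataConfig)
}

# Cache key: deterministic string of the study seed, data seed and purpose.
cachePath <- function(study, purpose) {
  if (is.null(study$outDir)) return(NULL)
  dataSeed <- if (!is.null(study$dataConfig)) study$dataConfig$seed else 0L
  file.path(study$outDir,
            sprintf("cache_s%d_d%d_%s.csv", study$seed, dataSeed, purpose))
}

mlpStudySpec <- function(study, seed, dropout = 0) {
  if (study$reduced)
    regressorSpec(hiddenSizes = c(64, 32), dropoutRate = dropout,
                  maxEpochs = 120, learningRate = 3e-3, batchSize = 128,
                  earlyStopPatience = 20, seed = seed)
  else
    regressorSpec(hiddenSizes = c(128, 64), dropoutRate = dropout,
                  maxEpochs = 300, learningRate = 1e-3, batchSize = 64,
                  earlyStopPatience = 20, seed = seed)
}

# Compute one estimator's UQEstimate on the test partition (cached).
studyEstimate <- function(study, method, data, split, pool) {
  cp <- cachePath(study, paste0("uq_", method))
  if (!is.null(cp) && file.exists(cp)) {
    est <- readUQEstimate(cp)
    poolEst <- readUQEstimate(sub("\\.csv$", "_pool.csv", cp))
    return(list(test = est, pool = poolEst))
  }
  train <- data[split$trainIdx]
  val <- data[split$valIdx]
  Xte <- descriptors(data)[split$testIdx, , drop = FALSE]
  idsTe <- molIds(data)[split$testIdx]
  Xpo <- descriptors(pool@pool)
  idsPo <- molIds(pool@pool)
  seed <- derivedSeed(study$seed, paste0("uq-", method))

  mk <- function(fTest, fPool) list(test = fTest, pool = fPool)
  res <- switch(method,
    gbm = {
      lo <- fitQuantileGbm(train, 0.1, seed)
      hi <- fitQuantileGbm(train, 0.9, seed)
      mu <- fitQuantileGbm(train, NA, seed, nrounds = 300, maxDepth = 4,
                           minChildWeight = 5, subsample = 0.8)
      mk(gbmQuantileUQ(predictGbm(lo, Xte), predictGbm(hi, Xte),
                       predictGbm(mu, Xte), idsTe),
         gbmQuantileUQ(predictGbm(lo, Xpo), predictGbm(hi, Xpo),
                       predictGbm(mu, Xpo), idsPo))
    },
    ensemble = {
      spec <- mlpStudySpec(study, seed)
      mk(ensembleUQ(spec, train, val, Xte, M = 5, ids = idsTe),
         ensembleUQ(spec, train, val, Xpo, M = 5, ids = idsPo))
    },
    mcdo = {
      m <- trainRegressor(mlpStudySpec(study, seed, dropout = 0.2), train, val,
                          head = "point")
      mk(mcdoUQ(m, Xte, T = 30, seed = seed, ids = idsTe),
         mcdoUQ(m, Xpo, T = 30, seed = seed, ids = idsPo))
    },
    mve = {
      m <- trainRegressor(mlpStudySpec(study, seed), train, val, head = "mve")
      mk(mveUQ(m, Xte, idsTe), mveUQ(m, Xpo, idsPo))
    },
    evidential = {
      m <- trainRegressor(mlpStudySpec(study, seed), train, val,
                          head = "evidential")
      mk(evidentialUQ(m, Xte, ids = idsTe), evidentialUQ(m, Xpo, ids = idsPo))
    },
    union = {
      m <- trainRegressor(mlpStudySpec(study, seed), train, val, head = "point")
      mk(unionUQ(m, train, Xte, seed = seed, ids = idsTe),
         unionUQ(m, train, Xpo, seed = seed, ids = idsPo))
    },
    knn_fp = mk(knnDensityUQ(descriptors(train), Xte, ids = idsTe,
                             method = "knn_fp"),
                knnDensityUQ(descriptors(train), Xpo, ids = idsPo,
                             method = "knn_fp")),
    knn_eb = mk(knnDensityUQ(embeddings(train),
                             embeddings(data)[split$testIdx, , drop = FALSE],
                             ids = idsTe, method = "knn_eb"),
                knnDensityUQ(embeddings(train), embeddings(pool@pool),
                             ids = idsPo, method = "knn_eb")),
    stop("configuration error: unknown method '", method, "'", call. = FALSE))
  if (!is.null(cp)) {
    writeUQEstimate(res$test, cp)
    writeUQEstimate(res$pool, sub("\\.csv$", "_pool.csv", cp))
  }
  res
}

#' Run the uncertainty-quantification evaluation study
#'
#' Generates (or loads) the dataset, builds a train/val/test split and a
#' uniform-similarity OOD pool, computes every configured estimator's
#' uncertainty on the test set and the pool, and reports the four metrics
#' per method: ENCE (NA for density methods), the error-UQ correlation,
#' the OOD correlation, and - when enabled - the leave-bin-out delta-error
#' correlation. The consensus row combines the quantile-GBM, MC-dropout
#' and MVE estimates.
#'
#' @param study a [studyConfig()].
#' @return data.frame with one row per method (columns `uqMethod`, `ence`,
#'   `rhoError`, `rhoOod`, `rhoDeltaError`).
#' @export
runUqEvaluation <- function(study) {
  if (!is.null(study$outDir) && !dir.exists(study$outDir))
    dir.create(study$outDir, recursive = TRUE)
  data <- studyData(study)
  n <- nMolecules(data)
  split <- randomSplit(n, c(0.7, 0.1, 0.2), study$seed)
  yTest <- targets(data)[split$testIdx]

  poolRaw <- makeOodPool(study$dataConfig, data[split$trainIdx],
                         nPool = max(5000, min(10000, 4 * n)),
                         seed = derivedSeed(study$seed, "study-pool"))
  sim <- similarityToTraining(descriptors(poolRaw), data[split$trainIdx],
                              subsetSize = 1000, seed = study$seed)
  pool <- new("OODPool", pool = poolRaw, similarity = sim)
  pool <- uniformSimilaritySample(pool, nOut = 400, seed = study$seed)

  methods <- study$uqMethods
  wantConsensus <- "consensus" %in% methods
  base <- setdiff(methods, "consensus")
  if (wantConsensus) base <- unique(c(base, "gbm", "mcdo", "mve"))
  ests <- lapply(base, function(m) studyEstimate(study, m, data, split, pool))
  names(ests) <- base
  if (wantConsensus) {
    members <- c("gbm", "mcdo", "mve")
    ests$consensus <- list(
      test = consensusUQ(lapply(ests[members], `[[`, "test")),
      pool = consensusUQ(lapply(ests[members], `[[`, "pool")))
  }

  rows <- lapply(intersect(methods, names(ests)), function(m) {
    e <- ests[[m]]
    enceVal <- enceValue(ence(e$test, yTest))
    rErr <- if (all(is.na(uqMean(e$test)))) NA_real_
            else rhoError(e$test, yTest)
    rOod <- rhoOod(e$pool, pool)
    rDelta <- NA_real_
    if (isTRUE(study$includeDeltaError) &&
        (m %in% c("knn_fp", "knn_eb") || !study$reduced)) {
      space <- if (m == "knn_eb") "embeddings" else "descriptors"
      rDelta <- runDeltaErrorStudy(
        data, nComponents = if (study$reduced) 1 else 3, nBins = 5,
        modelFamily = "gbm", uqSpace = space, seed = study$seed)$rho
    }
    data.frame(uqMethod = m, ence = enceVal, rhoError = rErr,
               rhoOod = rOod, rhoDeltaError = rDelta)
  })
  report <- do.call(rbind, rows)
  if (!is.null(study$outDir))
    write.csv(report, file.path(study$outDir, "uq_metrics.csv"),
              row.names = FALSE)
  report
}

#' Run the active-learning grid
#'
#' Executes [runAlExperiment()] over the configured (fraction, batch-size)
#' grid for the given leave-bin-out scenarios, collecting improvement
#' percentages, p-values and OOD sampling fractions.
#'
#' @param study a [studyConfig()].
#' @param scenarios data.frame with columns `pcIndex`, `binIndex`; default
#'   is component 1, bins 1..3 when `reduced`, else the full 3 x 5 grid.
#' @param samplers acquisition strategies.
#' @param uqMethod pool-uncertainty source.
#' @return data.frame with one row per (fraction, nAdd, scenario, sampler,
#'   subset).
#' @export
runAlGrid <- function(study, scenarios = NULL,
                      samplers = c("uq_weighted", "ood_only"),
                      uqMethod = "knn_fp") {
  if (is.null(scenarios)) {
    scenarios <- if (study$reduced)
      data.frame(pcIndex = 1L, binIndex = 1:3)
    else expand.grid(pcIndex = 1:3, binIndex = 1:5)
  }
  data <- studyData(study)
  rows <- list()
  for (f in study$alFractions) for (na in study$alNAdds)
    for (s in seq_len(nrow(scenarios))) {
      cfg <- alConfig(initialFraction = f, nAdd = na, samplers = samplers,
                      uqMethod = uqMethod, scenario = "leave_bin_out",
                      pcIndex = scenarios$pcIndex[s],
                      binIndex = scenarios$binIndex[s],
                      nReps = study$alReps, seed = study$seed)
      out <- runAlExperiment(cfg, data)
      imp <- out@improvement
      if (nrow(imp)) {
        imp$initialFraction <- f; imp$nAdd <- na
        imp$pcIndex <- scenarios$pcIndex[s]; imp$binIndex <- scenarios$binIndex[s]
        rows[[length(rows) + 1L]] <- imp
      }
    }
  res <- do.call(rbind, rows)
  if (!is.null(study$outDir)) {
    if (!dir.exists(study$outDir)) dir.create(study$outDir, recursive = TRUE)
    write.csv(res, file.path(study$outDir, "al_grid.csv"), row.names = FALSE)
  }
  res
}

#' Write study reports with a reproducibility manifest
#'
#' Writes each table as CSV and JSON plus a `manifest.json` recording the
#' study seed, configuration and session versions, sufficient to re-run
#' the study identically.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory.
#' @param study optional [studyConfig()] recorded in the manifest.
#' @return paths of the written files, invisibly.
#' @export
writeReport <- function(tables, outDir, study = NULL) {
  if (length(tables) == 0L || any(!vapply(tables, nrow, 1L)))
    stop("input error: empty table(s)", call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p1 <- file.path(outDir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p1, row.names = FALSE)
    p2 <- file.path(outDir, paste0(nm, ".json"))
    jsonlite::write_json(tables[[nm]], p2, dataframe = "rows", digits = NA)
    paths <- c(paths, p1, p2)
  }
  manifest <- list(
    seed = if (!is.null(study)) study$seed else NA,
    dataConfig = if (!is.null(study)) unclass(study$dataConfig) else NULL,
    uqMethods = if (!is.null(study)) study$uqMethods else NULL,
    rVersion = as.character(getRversion()),
    packageVersion = as.character(utils::packageVersion("molUQ")),
    tables = names(tables))
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
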