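#' Configuration for the single-iteration active-learning experiment
#'
#' @param initialFraction fraction of the dataset used as the initial
#'   training sample (grid default in the study: 0.05, 0.10, 0.20, 0.40).
#' @param nAdd number of molecules added in the active-learning step
#'   (grid default: 25, 50, 100, 250, 500, 1000).
#' @param samplers acquisition strategies to run alongside the paired
#'   random arm: any of `"uq_weighted"`, `"diversity"`, `"ood_only"`,
#'   `"random"`.
#' @param uqMethod pool-uncertainty source for `uq_weighted`: `"knn_fp"`
#'   (descriptor-space density), `"knn_eb"` (embedding-space density) or
#'   `"gbm"` (quantile-interval width).
#' @param scenario `"leave_bin_out"` (a PCA bin is excised from the initial
#'   sample, remaining in the pool and test set) or `"standard"`.
#' @param pcIndex,binIndex which bin to excise (leave_bin_out only).
#' @param nReps paired repetitions (>= 2; the study uses 30).
#' @param modelFamily `"gbm"` (fast default) or `"mlp"`.
#' @param testFraction held-out test fraction.
#' @param seed master seed; per-repetition streams derive from it.
#' @return an `ALConfig` list.
#' @export
alConfig <- function(initialFraction = 0.1, nAdd = 100,
                     samplers = c("uq_weighted"), uqMethod = "knn_fp",
                     scenario = c("leave_bin_out", "standard"),
                     pcIndex = 1, binIndex = 1, nReps = 30,
                     modelFamily = "gbm", testFraction = 0.2, seed = 1) {
  scenario <- match.arg(scenario)
  if (initialFraction <= 0 || initialFraction >= 1)
    stop("configuration error: initialFraction must lie in (0,1)", call. = FALSE)
  if (nAdd < 1) stop("configuration error: nAdd must be positive", call. = FALSE)
  if (nReps < 2) stop("configuration error: nReps must be >= 2 for t-tests",
                      call. = FALSE)
  ok <- c("uq_weighted", "diversity", "ood_only", "random")
  if (!all(samplers %in% ok))
    stop("configuration error: unknown sampler(s); valid: ",
         paste(ok, collapse = ", "), call. = FALSE)
  list(initialFraction = initialFraction, nAdd = as.integer(nAdd),
       samplers = samplers, uqMethod = uqMethod, scenario = scenario,
       pcIndex = as.integer(pcIndex), binIndex = as.integer(binIndex),
       nReps = as.integer(nReps), modelFamily = modelFamily,
       testFraction = testFraction, seed = as.integer(seed))
}

#' Select an acquisition batch from the candidate pool
#'
#' Without-replacement sampling of `n` pool members. `uq_weighted` draws
#' sequentially with probability proportional to the uncertainty,
#' renormalizing after each draw (linear weighting: twice the uncertainty,
#' twice the selection probability at each draw). `random` is uniform.
#' `diversity` weights by each member's mean pairwise distance to the rest
#' of the pool. `ood_only` samples uniformly from the removed-bin members
#' only, capping at their count with a warning if `n` exceeds it.
#'
#' @param poolSigma nonnegative uncertainty per pool member.
#' @param n batch size (<= pool size).
#' @param strategy one of `"uq_weighted"`, `"random"`, `"diversity"`,
#'   `"ood_only"`.
#' @param poolMeta list with optional elements `oodFlags` (logical, needed
#'   by ood_only) and `diversity` (nonnegative weights, needed by
#'   diversity).
#' @param seed draw seed.
#' @return integer indices into the pool.
#' @export
selectBatch <- function(poolSigma, n, strategy = c("uq_weighted", "random",
                                                   "diversity", "ood_only"),
                        poolMeta = list(), seed = 1) {
  strategy <- match.arg(strategy)
  m <- length(poolSigma)
  if (n > m) stop("configuration error: batch exceeds pool size", call. = FALSE)
  withSeed(derivedSeed(seed, paste0("select-", strategy)), {
    if (strategy == "uq_weighted") {
      if (all(poolSigma == 0))
        stop("degenerate weights: all pool uncertainties are zero", call. = FALSE)
      sample.int(m, n, prob = poolSigma)
    } else if (strategy == "random") {
      sample.int(m, n)
    } else if (strategy == "diversity") {
      w <- poolMeta$diversity
      if (is.null(w) || all(w == 0))
        stop("degenerate weights: diversity weights missing or all zero",
             call. = FALSE)
      sample.int(m, n, prob = w)
    } else {
      flags <- poolMeta$oodFlags
      if (is.null(flags)) stop("input error: ood_only needs oodFlags", call. = FALSE)
      cand <- which(flags)
      if (n > length(cand)) {
        warning("ood_only batch capped at the removed-bin pool size (",
                length(cand), ")")
        n <- length(cand)
      }
      cand[sample.int(length(cand), n)]
    }
  })
}

#' Fraction of a batch drawn from the removed (OOD) bin
#'
#' @param batch integer pool indices of the selected batch.
#' @param removedIdx pool indices belonging to the removed bin.
#' @return fraction in \[0,1\].
#' @export
fractionOodSampled <- function(batch, removedIdx) {
  if (length(batch) == 0L) stop("input error: empty batch", call. = FALSE)
  length(intersect(batch, removedIdx)) / length(batch)
}

#' Mean percentage RMSE improvement over the paired random arm
#'
#' `100 * mean((rmseRandom - rmseAl) / rmseRandom)` over repetitions.
#'
#' @param rmseAl,rmseRandom paired per-repetition RMSE vectors.
#' @return scalar percentage.
#' @export
improvementPct <- function(rmseAl, rmseRandom) {
  if (length(rmseAl) != length(rmseRandom))
    stop("input error: arms must be paired", call. = FALSE)
  if (any(rmseRandom == 0))
    stop("degenerate: zero RMSE in the random arm", call. = FALSE)
  100 * mean((rmseRandom - rmseAl) / rmseRandom)
}

#' Paired one-sided t-test for active learning beating random sampling
#'
#' Tests the alternative `mean(rmseRandom - rmseAl) > 0`. Zero-variance
#' differences give a degenerate flagged result with `p = NA`.
#'
#' @param rmseAl,rmseRandom paired per-repetition RMSE vectors (>= 2 pairs).
#' @return list with `t`, `p`, `degenerate`.
#' @export
pairedOneSidedT <- function(rmseAl, rmseRandom) {
  if (length(rmseAl) != length(rmseRandom) || length(rmseAl) < 2L)
    stop("input error: need >= 2 paired repetitions", call. = FALSE)
  d <- rmseRandom - rmseAl
  if (sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  tt <- t.test(rmseRandom, rmseAl, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), p = unname(tt$p.value), degenerate = FALSE)
}

# Pool uncertainty under the configured UQ method, given the current
# training subset.
poolUncertainty <- function(uqMethod, data, trainIdx, poolIdx, seed) {
  if (uqMethod == "knn_fp") {
    uqSigma(knnDensityUQ(descriptors(data)[trainIdx, , drop = FALSE],
                         descriptors(data)[poolIdx, , drop = FALSE]))
  } else if (uqMethod == "knn_eb") {
    uqSigma(knnDensityUQ(embeddings(data)[trainIdx, , drop = FALSE],
                         embeddings(data)[poolIdx, , drop = FALSE]))
  } else if (uqMethod == "gbm") {
    tr <- data[trainIdx]
    lo <- fitQuantileGbm(tr, 0.1, seed = seed)
    hi <- fitQuantileGbm(tr, 0.9, seed = seed)
    Xp <- descriptors(data)[poolIdx, , drop = FALSE]
    pmax((predictGbm(hi, Xp) - predictGbm(lo, Xp)) / 2, 0)
  } else stop("configuration error: unknown uqMethod '", uqMethod,
              "'; valid: knn_fp, knn_eb, gbm", call. = FALSE)
}

#' Run the single-iteration active-learning experiment
#'
#' Per repetition: draw a seeded initial training sample (for the
#' leave-bin-out scenario the removed bin's molecules are excluded from the
#' initial sample but stay in the candidate pool and the test set), train
#' the model, score the pool with the configured UQ method, select a batch
#' per strategy, augment, retrain, and evaluate the test RMSE on the OOD
#' bin, the in-distribution bins, and the whole test set. Every strategy's
#' arm shares the repetition's initial training sample with the random
#' arm, so the comparison is paired.
#'
#' @param config an [alConfig()].
#' @param data a [MoleculeSet].
#' @return an [ALOutcome].
#' @export
runAlExperiment <- function(config, data) {
  n <- nMolecules(data)
  split <- randomSplit(n, c(1 - config$testFraction, 0, config$testFraction),
                       config$seed)
  candIdx <- sort(c(split$trainIdx, split$valIdx))
  testIdx <- split$testIdx

  if (config$scenario == "leave_bin_out") {
    assignments <- pcaTopBins(descriptors(data), max(3, config$pcIndex), 5)
    binOf <- assignments[[config$pcIndex]]@binOf
    inBin <- binOf == config$binIndex
  } else {
    inBin <- rep(FALSE, n)
  }
  testOod <- testIdx[inBin[testIdx]]
  testId <- setdiff(testIdx, testOod)
  Xtest <- descriptors(data)[testIdx, , drop = FALSE]
  yTest <- targets(data)[testIdx]

  nInit <- max(2L, round(config$initialFraction * n))
  samplers <- unique(c(config$samplers, "random"))
  repRows <- list(); fracRows <- list()

  for (r in seq_len(config$nReps)) {
    repSeed <- derivedSeed(config$seed, paste0("al-rep-", r))
    initPool <- if (config$scenario == "leave_bin_out")
      candIdx[!inBin[candIdx]] else candIdx
    initIdx <- withSeed(derivedSeed(repSeed, "initial-train"),
                        sort(sample(initPool, min(nInit, length(initPool)))))
    poolIdx <- setdiff(candIdx, initIdx)
    nAdd <- min(config$nAdd, length(poolIdx))

    needUq <- "uq_weighted" %in% samplers
    sigmaPool <- if (needUq)
      poolUncertainty(config$uqMethod, data, initIdx, poolIdx,
                      derivedSeed(repSeed, "pool-uq")) else rep(1, length(poolIdx))
    poolMeta <- list(oodFlags = inBin[poolIdx])
    if ("diversity" %in% samplers) {
      Ep <- embeddings(data)[poolIdx, , drop = FALSE]
      simP <- (1 + cosineCross(Ep, Ep)) / 2
      poolMeta$diversity <- rowMeans(2 * (1 - simP))
    }

    for (strat in samplers) {
      batch <- selectBatch(sigmaPool, nAdd, strat, poolMeta,
                           seed = derivedSeed(repSeed, paste0("batch-", strat)))
      augIdx <- sort(c(initIdx, poolIdx[batch]))
      fit <- fitMeanModel(config$modelFamily, data[augIdx],
                          derivedSeed(repSeed, "model"))
      pred <- fit$predict(Xtest)
      subsetRmse <- function(sub) {
        pos <- match(sub, testIdx)
        if (length(pos) >= 1L) rmse(yTest[pos], pred[pos]) else NA_real_
      }
      repRows[[length(repRows) + 1L]] <- data.frame(
        rep = r, sampler = strat,
        subset = c("ood_bin", "id_bins", "whole"),
        rmse = c(if (length(testOod)) subsetRmse(testOod) else NA_real_,
                 subsetRmse(testId), subsetRmse(testIdx)))
      fracRows[[length(fracRows) + 1L]] <- data.frame(
        rep = r, sampler = strat,
        fracOod = if (config$scenario == "leave_bin_out")
          fractionOodSampled(batch, which(inBin[poolIdx])) else NA_real_)
    }
  }

  reps <- do.call(rbind, repRows)
  fracOod <- do.call(rbind, fracRows)
  impRows <- list()
  for (strat in setdiff(samplers, "random")) {
    for (sub in unique(reps$subset)) {
      a <- reps$rmse[reps$sampler == strat & reps$subset == sub]
      b <- reps$rmse[reps$sampler == "random" & reps$subset == sub]
      if (anyNA(a) || anyNA(b)) next
      tt <- pairedOneSidedT(a, b)
      impRows[[length(impRows) + 1L]] <- data.frame(
        sampler = strat, subset = sub,
        improvementPct = improvementPct(a, b), p = tt$p,
        degenerate = tt$degenerate)
    }
  }
  new("ALOutcome", reps = reps,
      improvement = if (length(impRows)) do.call(rbind, impRows) else data.frame(),
      fracOod = fracOod, config = config)
}

#' Enumerate the active-learning experiment grid
#'
#' @param fractions initial-training fractions.
#' @param nAdds batch sizes.
#' @param nComponents,nBins leave-bin-out scenario grid.
#' @return data.frame with one row per (fraction, nAdd, pcIndex, binIndex);
#'   with the default grids: 24 combinations x 15 scenarios = 360 rows.
#' @export
enumerateAlGrid <- function(fractions = c(0.05, 0.10, 0.20, 0.40),
                            nAdds = c(25, 50, 100, 250, 500, 1000),
                            nComponents = 3, nBins = 5) {
  expand.grid(initialFraction = fractions, nAdd = nAdds,
              pcIndex = seq_len(nComponents), binIndex = seq_len(nBins),
              KEEP.OUT.ATTRS = FALSE)
}

#' Summarize active-learning outcomes over a configuration grid
#'
#' @param outcomes data.frame with one row per (initialFraction, nAdd,
#'   pcIndex, binIndex, sampler, subset) carrying `improvementPct` and `p`.
#' @return list with `byFraction` and `byNAdd` mean-improvement tables, a
#'   Table-6-shaped `bySamplerSubset` summary, and the grid `counts`
#'   (combinations, scenarios, experiments).
#' @export
alGridSummary <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L)
    stop("input error: empty outcome table", call. = FALSE)
  agg <- function(byCols) {
    stats::aggregate(outcomes["improvementPct"], by = outcomes[byCols],
                     FUN = mean)
  }
  combos <- unique(outcomes[c("initialFraction", "nAdd")])
  scen <- unique(outcomes[c("pcIndex", "binIndex")])
  list(byFraction = agg(c("initialFraction", "subset")),
       byNAdd = agg(c("nAdd", "subset")),
       bySamplerSubset = agg(c("sampler", "subset")),
       counts = c(combinations = nrow(combos), scenarios = nrow(scen),
                  experiments = nrow(unique(outcomes[c("initialFraction",
                                                       "nAdd", "pcIndex",
                                                       "binIndex")]))))
}

#' Correlate active-learning improvements with UQ metric values
#'
#' Joins a metric table and an AL improvement table by UQ method and
#' correlates each metric column against the improvement on each test
#' subset.
#'
#' @param metricTable data.frame with a `uqMethod` column and numeric
#'   metric columns.
#' @param alTable data.frame with `uqMethod`, `subset`, `improvementPct`.
#' @param method correlation type.
#' @return matrix (metrics x subsets) of correlations.
#' @export
correlateAlWithUq <- function(metricTable, alTable, method = "pearson") {
  subsets <- unique(alTable$subset)
  metrics <- names(metricTable)[vapply(metricTable, is.numeric, logical(1))]
  common <- intersect(metricTable$uqMethod, alTable$uqMethod)
  if (length(common) < 3L)
    stop("insufficient data: need >= 3 matched UQ methods", call. = FALSE)
  out <- matrix(NA_real_, length(metrics), length(subsets),
                dimnames = list(metrics, subsets))
  mt <- metricTable[match(common, metricTable$uqMethod), ]
  for (sub in subsets) {
    at <- alTable[alTable$subset == sub, ]
    imp <- at$improvementPct[match(common, at$uqMethod)]
    for (m in metrics) {
      v <- mt[[m]]
      keep <- is.finite(v) & is.finite(imp)
      if (sum(keep) >= 3L)
        out[m, sub] <- suppressWarnings(cor(v[keep], imp[keep], method = method))
    }
  }
  out
}
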