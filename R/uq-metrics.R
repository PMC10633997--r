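#' Root mean square error
#'
#' @param yTrue,yPred equal-length numeric vectors.
#' @return `sqrt(mean((yTrue - yPred)^2))`.
#' @export
rmse <- function(yTrue, yPred) {
  if (length(yTrue) == 0L || length(yTrue) != length(yPred))
    stop("input error: need equal-length nonempty vectors", call. = FALSE)
  sqrt(mean((yTrue - yPred)^2))
}

#' Expected normalized calibration error
#'
#' Sorts molecules by predicted uncertainty, forms `nBins` equal-count
#' bins, and compares the root mean variance of the predicted sigmas
#' (RMV) with the empirical RMSE inside each bin:
#' `ENCE = mean_j |RMV(j) - RMSE(j)| / RMV(j)`.
#' Zero means the predicted uncertainty level matches the observed error
#' level in every bin. For an uncalibrated (density) estimate the metric
#' is not applicable and `ence` is NA.
#'
#' @param estimate a [UQEstimate].
#' @param yTrue observed targets aligned with the estimate.
#' @param nBins number of equal-count bins (default 10).
#' @return a [CalibrationBins].
#' @export
ence <- function(estimate, yTrue, nBins = 10) {
  stopifnot(is(estimate, "UQEstimate"))
  if (!isCalibrated(estimate))
    return(new("CalibrationBins", nBins = 0L,
               bins = data.frame(), ence = NA_real_))
  sigma <- uqSigma(estimate)
  n <- length(sigma)
  if (length(yTrue) != n)
    stop("input error: yTrue must align with the estimate", call. = FALSE)
  if (n < nBins)
    stop("input error: need at least nBins molecules", call. = FALSE)
  binId <- rankBins(sigma, nBins)
  err2 <- (yTrue - uqMean(estimate))^2
  rows <- lapply(seq_len(nBins), function(j) {
    inBin <- binId == j
    rmv <- sqrt(mean(sigma[inBin]^2))
    if (rmv == 0)
      stop("degenerate bin: RMV is zero in bin ", j, call. = FALSE)
    data.frame(bin = j, n = sum(inBin),
               sigmaLo = min(sigma[inBin]), sigmaHi = max(sigma[inBin]),
               rmv = rmv, rmse = sqrt(mean(err2[inBin])))
  })
  bins <- do.call(rbind, rows)
  new("CalibrationBins", nBins = as.integer(nBins), bins = bins,
      ence = mean(abs(bins$rmv - bins$rmse) / bins$rmv))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank);
#' invariant under strictly increasing transforms of either argument.
#'
#' @param a,b equal-length numeric vectors (length >= 3, non-constant).
#' @return correlation in \[-1,1\].
#' @export
spearmanRho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("input error: need equal lengths >= 3", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  cor(a, b, method = "spearman")
}

#' Error-uncertainty rank correlation
#'
#' Spearman correlation between per-molecule absolute prediction errors
#' and predicted uncertainties; positive values mean the estimator ranks
#' its own errors correctly.
#'
#' @param estimate a [UQEstimate] (needs finite means).
#' @param yTrue observed targets.
#' @return scalar correlation.
#' @export
rhoError <- function(estimate, yTrue) {
  stopifnot(is(estimate, "UQEstimate"))
  spearmanRho(abs(yTrue - uqMean(estimate)), uqSigma(estimate))
}

#' Out-of-distribution rank correlation
#'
#' Spearman correlation between uncertainty and dissimilarity
#' `(1 - similarity-to-training)` over a uniform-similarity pool. The sign
#' convention makes "dissimilar molecules get higher uncertainty" positive,
#' so larger is better.
#'
#' @param estimate a [UQEstimate] evaluated on the pool molecules.
#' @param pool an [OODPool] (after uniform-similarity downsampling).
#' @return scalar correlation.
#' @export
rhoOod <- function(estimate, pool) {
  stopifnot(is(estimate, "UQEstimate"), is(pool, "OODPool"))
  spearmanRho(uqSigma(estimate), 1 - pool@similarity)
}

#' Delta-error / delta-uncertainty correlation over leave-bin-out scenarios
#'
#' Given, for each (component, bin) scenario, the removed-bin test RMSE and
#' mean uncertainty under both the full model and the bin-removed model,
#' computes `dRMSE = rmseRemoved - rmseFull` and `dUQ = uqRemoved - uqFull`
#' per scenario and the Spearman correlation across scenarios.
#'
#' @param scenarios data.frame with columns `pcIndex`, `binIndex`,
#'   `rmseFull`, `rmseRemoved`, `uqFull`, `uqRemoved` (one row per
#'   scenario; any incomplete row is an error).
#' @return list with `rho` and the per-scenario `table` (deltas appended).
#' @export
rhoDeltaError <- function(scenarios) {
  need <- c("pcIndex", "binIndex", "rmseFull", "rmseRemoved", "uqFull", "uqRemoved")
  if (!all(need %in% names(scenarios)))
    stop("input error: missing scenario columns", call. = FALSE)
  if (anyNA(scenarios[need]))
    stop("input error: incomplete scenario rows", call. = FALSE)
  scenarios$dRmse <- scenarios$rmseRemoved - scenarios$rmseFull
  scenarios$dUq <- scenarios$uqRemoved - scenarios$uqFull
  list(rho = spearmanRho(scenarios$dRmse, scenarios$dUq), table = scenarios)
}

#' Cross-correlation of UQ metrics across estimator rows
#'
#' Pairwise correlation between metric columns over a table of metric
#' suites (rows = estimator/model/property combinations). Constant columns
#' yield NA with a warning rather than an error, mirroring the undefined
#' correlation of duplicated rows.
#'
#' @param suites data.frame whose numeric columns are metrics (e.g.
#'   `ence`, `rhoError`, `rhoOod`, `rhoDeltaError`); non-numeric columns
#'   are ignored.
#' @param method correlation type passed to [stats::cor()].
#' @return symmetric correlation matrix.
#' @export
metricCrossCorrelation <- function(suites, method = "pearson") {
  num <- suites[vapply(suites, is.numeric, logical(1))]
  if (ncol(num) < 2L || nrow(num) < 3L)
    stop("input error: need >= 3 rows and >= 2 numeric metric columns",
         call. = FALSE)
  if (all(vapply(num, function(x) all(is.na(x)), logical(1))))
    stop("input error: all-missing metric columns", call. = FALSE)
  const <- vapply(num, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    warning("constant metric column(s): ",
            paste(names(num)[const], collapse = ", "),
            " produce undefined correlations")
  suppressWarnings(cor(as.matrix(num), use = "pairwise.complete.obs",
                       method = method))
}
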