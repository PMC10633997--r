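#' MoleculeSet: a tabular molecular regression dataset
#'
#' Container for a QSAR-style regression dataset: unique molecule
#' identifiers, a numeric descriptor matrix `X` (n x p), an optional
#' embedding matrix `E` (n x q, a second learned-representation block),
#' the real-valued target `y`, integer cluster labels, and - for synthetic
#' data only - the known per-molecule noise scale `sigmaTrue`.
#'
#' @slot ids character vector of unique molecule identifiers.
#' @slot X numeric descriptor matrix, one row per molecule.
#' @slot E numeric embedding matrix, one row per molecule (may have 0 cols).
#' @slot y numeric target vector.
#' @slot cluster integer cluster labels.
#' @slot sigmaTrue nonnegative per-molecule noise sd (NA when unknown).
#'
#' @seealso [generateDataset()], [readMoleculeSet()]
#' @name MoleculeSet
#' @aliases MoleculeSet MoleculeSet-class
#' @export
setClass("MoleculeSet",
  representation(ids = "character", X = "matrix", E = "matrix",
                 y = "numeric", cluster = "integer", sigmaTrue = "numeric"),
  validity = function(object) {
    n <- length(object@ids)
    msg <- character()
    if (anyDuplicated(object@ids)) msg <- c(msg, "molecule ids must be unique")
    if (nrow(object@X) != n) msg <- c(msg, "nrow(X) != length(ids)")
    if (nrow(object@E) != n) msg <- c(msg, "nrow(E) != length(ids)")
    if (length(object@y) != n) msg <- c(msg, "length(y) != length(ids)")
    if (length(object@cluster) != n) msg <- c(msg, "length(cluster) != length(ids)")
    if (length(object@sigmaTrue) != n) msg <- c(msg, "length(sigmaTrue) != length(ids)")
    if (any(object@sigmaTrue < 0, na.rm = TRUE)) msg <- c(msg, "sigmaTrue must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' UQEstimate: a per-molecule uncertainty estimate
#'
#' The common contract every uncertainty estimator in the package honours:
#' a predicted mean, a nonnegative uncertainty value `sigma` per molecule,
#' and a `calibrated` flag. Calibrated estimators report `sigma` on the
#' error scale of the target (a standard deviation); density estimators
#' report only a relative score and set `calibrated = FALSE`, which makes
#' the ENCE metric not applicable to them.
#'
#' @slot ids character molecule identifiers.
#' @slot mean numeric predicted property (NA allowed for density methods
#'   used without a base predictor).
#' @slot sigma nonnegative numeric uncertainty values.
#' @slot calibrated logical scalar; FALSE exactly for density methods.
#' @slot method character tag naming the estimator.
#' @name UQEstimate
#' @aliases UQEstimate UQEstimate-class
#' @export
setClass("UQEstimate",
  representation(ids = "character", mean = "numeric", sigma = "numeric",
                 calibrated = "logical", method = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@ids)
    if (length(object@mean) != n) msg <- c(msg, "length(mean) != length(ids)")
    if (length(object@sigma) != n) msg <- c(msg, "length(sigma) != length(ids)")
    if (any(object@sigma < 0, na.rm = TRUE)) msg <- c(msg, "sigma must be >= 0")
    if (length(object@calibrated) != 1L) msg <- c(msg, "calibrated must be a scalar")
    if (length(msg)) msg else TRUE
  })

#' BinAssignment: percentile bins along one principal component
#'
#' @slot pcIndex integer, which principal component (1-based).
#' @slot binEdges the four interior percentile cut points (20/40/60/80%).
#' @slot binOf integer bin label in 1..nBins for every molecule.
#' @name BinAssignment
#' @aliases BinAssignment BinAssignment-class
#' @export
setClass("BinAssignment",
  representation(pcIndex = "integer", binEdges = "numeric", binOf = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@binEdges)) msg <- c(msg, "binEdges must be nondecreasing")
    if (length(msg)) msg else TRUE
  })

#' LeaveBinOutSplit: a train/val/test split with one PCA bin excised
#'
#' @slot pcIndex,binIndex which (component, bin) scenario this is.
#' @slot trainIdx,valIdx,testIdx disjoint integer index sets; the removed
#'   bin's members are absent from train and val, test is untouched.
#' @slot removedIdx indices of bin members that were removed from train/val.
#' @name LeaveBinOutSplit
#' @aliases LeaveBinOutSplit LeaveBinOutSplit-class
#' @export
setClass("LeaveBinOutSplit",
  representation(pcIndex = "integer", binIndex = "integer",
                 trainIdx = "integer", valIdx = "integer",
                 testIdx = "integer", removedIdx = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(intersect(object@trainIdx, object@valIdx)) ||
        length(intersect(object@trainIdx, object@testIdx)) ||
        length(intersect(object@valIdx, object@testIdx)))
      msg <- c(msg, "train/val/test must be disjoint")
    if (length(intersect(c(object@trainIdx, object@valIdx), object@removedIdx)))
      msg <- c(msg, "removed bin members must not appear in train or val")
    if (length(msg)) msg else TRUE
  })

#' OODPool: candidate molecules scored by similarity to the training set
#'
#' @slot pool a [MoleculeSet] of candidate molecules.
#' @slot similarity per-molecule maximum similarity (in \[0,1\]) to a random
#'   subset of the training data.
#' @name OODPool
#' @aliases OODPool OODPool-class
#' @export
setClass("OODPool",
  representation(pool = "MoleculeSet", similarity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@similarity) != length(object@pool@ids))
      msg <- c(msg, "similarity length must match pool size")
    if (any(object@similarity < -1e-12 | object@similarity > 1 + 1e-12))
      msg <- c(msg, "similarity must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' CalibrationBins: ENCE decomposition over uncertainty-sorted bins
#'
#' Per-bin root mean variance (RMV), empirical RMSE, counts and sigma
#' intervals, plus the scalar expected normalized calibration error. For an
#' uncalibrated (density) estimate `ence` is NA and the bin table is empty.
#'
#' @slot nBins integer number of equal-count bins.
#' @slot bins data.frame with columns bin, n, sigmaLo, sigmaHi, rmv, rmse.
#' @slot ence nonnegative scalar, or NA when not applicable.
#' @name CalibrationBins
#' @aliases CalibrationBins CalibrationBins-class
#' @export
setClass("CalibrationBins",
  representation(nBins = "integer", bins = "data.frame", ence = "numeric"),
  validity = function(object) {
    if (!is.na(object@ence) && object@ence < 0) "ence must be >= 0" else TRUE
  })

#' ALOutcome: results of one active-learning experiment
#'
#' @slot reps data.frame, one row per (repetition, sampler, subset) with the
#'   post-augmentation test RMSE.
#' @slot improvement data.frame per (sampler, subset): mean percentage
#'   improvement in RMSE over the paired random arm and the one-sided p-value.
#' @slot fracOod data.frame per (repetition, sampler): fraction of the
#'   selected batch that came from the removed (OOD) bin; NA for the
#'   standard (no removed bin) scenario.
#' @slot config list, the ALConfig used.
#' @name ALOutcome
#' @aliases ALOutcome ALOutcome-class
#' @export
setClass("ALOutcome",
  representation(reps = "data.frame", improvement = "data.frame",
                 fracOod = "data.frame", config = "list"))

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", length(object@ids), "molecules\n")
  cat("  descriptors:", ncol(object@X), " embeddings:", ncol(object@E),
      " clusters:", length(unique(object@cluster)), "\n")
  cat("  target range: [", signif(min(object@y), 4), ",",
      signif(max(object@y), 4), "]\n")
  if (!all(is.na(object@sigmaTrue)))
    cat("  known noise sd range: [", signif(min(object@sigmaTrue), 4), ",",
        signif(max(object@sigmaTrue), 4), "]\n")
})

setMethod("show", "UQEstimate", function(object) {
  cat("UQEstimate [", object@method, "] for", length(object@ids), "molecules\n")
  cat("  calibrated:", object@calibrated,
      " sigma range: [", signif(min(object@sigma), 4), ",",
      signif(max(object@sigma), 4), "]\n")
})

setMethod("show", "CalibrationBins", function(object) {
  if (is.na(object@ence)) {
    cat("CalibrationBins: ENCE not applicable (uncalibrated estimate)\n")
  } else {
    cat("CalibrationBins:", object@nBins, "bins, ENCE =",
        signif(object@ence, 4), "\n")
  }
})

setMethod("show", "ALOutcome", function(object) {
  cat("ALOutcome:", length(unique(object@reps$rep)), "repetitions,",
      "samplers:", paste(unique(object@reps$sampler), collapse = ", "), "\n")
  print(object@improvement)
})

#' Accessors for MoleculeSet and UQEstimate slots
#'
#' @param object a [MoleculeSet] or [UQEstimate].
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
molIds <- function(object) object@ids
#' @rdname accessors
#' @export
descriptors <- function(object) object@X
#' @rdname accessors
#' @export
embeddings <- function(object) object@E
#' @rdname accessors
#' @export
targets <- function(object) object@y
#' @rdname accessors
#' @export
clusterLabels <- function(object) object@cluster
#' @rdname accessors
#' @export
trueNoise <- function(object) object@sigmaTrue
#' @rdname accessors
#' @export
nMolecules <- function(object) length(object@ids)
#' @rdname accessors
#' @export
uqSigma <- function(object) object@sigma
#' @rdname accessors
#' @export
uqMean <- function(object) object@mean
#' @rdname accessors
#' @export
isCalibrated <- function(object) object@calibrated
#' @rdname accessors
#' @export
uqMethod <- function(object) object@method
#' @rdname accessors
#' @export
enceValue <- function(object) object@ence

#' Subset a MoleculeSet by molecule index
#'
#' @param x a [MoleculeSet].
#' @param i integer or logical index over molecules.
#' @param j,...,drop ignored.
#' @return the subsetted [MoleculeSet].
#' @name subset-MoleculeSet
#' @aliases [,MoleculeSet-method [,MoleculeSet,ANY,ANY,ANY-method
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  new("MoleculeSet", ids = x@ids[i], X = x@X[i, , drop = FALSE],
      E = x@E[i, , drop = FALSE], y = x@y[i], cluster = x@cluster[i],
      sigmaTrue = x@sigmaTrue[i])
})
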