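#' Percentile bins along the top principal components
#'
#' Runs PCA on the z-scored descriptor matrix of the full dataset and, for
#' each of the top `nComponents` components, partitions the molecules into
#' `nBins` equally sized bins by component-value percentiles. Binning is
#' rank-based with a stable first-index tie-break, so bin sizes differ by
#' at most one even under ties. With 3 components and 5 bins this yields
#' the 15 leave-bin-out scenarios used by the delta-error metric and the
#' generalization active-learning experiment.
#'
#' @param X descriptor matrix (raw scale; z-scored internally with
#'   full-data statistics).
#' @param nComponents number of leading components (default 3).
#' @param nBins bins per component (default 5).
#' @return list of [BinAssignment], one per component.
#' @export
pcaTopBins <- function(X, nComponents = 3, nBins = 5) {
  if (nrow(X) < nBins)
    stop("input error: need at least nBins molecules", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (all(sds == 0))
    stop("degenerate PCA: constant feature matrix", call. = FALSE)
  Xs <- applyScaler(fitScaler(X), X)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  nComponents <- min(nComponents, ncol(pc$x))
  lapply(seq_len(nComponents), function(i) {
    score <- pc$x[, i]
    new("BinAssignment", pcIndex = i,
        binEdges = as.numeric(quantile(score, seq_len(nBins - 1L) / nBins)),
        binOf = rankBins(score, nBins))
  })
}

#' Excise one PCA bin from the training and validation sets
#'
#' Removes the members of bin `binIndex` (along the component of
#' `assignment`) from the training and validation index sets of a full
#' split; the test set is untouched, so test molecules inside the bin
#' become artificial out-of-distribution cases.
#'
#' @param fullSplit list with integer elements `trainIdx`, `valIdx`,
#'   `testIdx` (disjoint).
#' @param assignment a [BinAssignment].
#' @param binIndex bin to remove (1..nBins).
#' @return a [LeaveBinOutSplit].
#' @export
leaveBinOut <- function(fullSplit, assignment, binIndex) {
  nBins <- max(assignment@binOf)
  if (binIndex < 1 || binIndex > nBins)
    stop("input error: binIndex out of range", call. = FALSE)
  members <- which(assignment@binOf == binIndex)
  trainIdx <- setdiff(fullSplit$trainIdx, members)
  valIdx <- setdiff(fullSplit$valIdx, members)
  if (length(trainIdx) == 0L)
    stop("configuration error: removing the bin empties the training set",
         call. = FALSE)
  new("LeaveBinOutSplit", pcIndex = assignment@pcIndex,
      binIndex = as.integer(binIndex),
      trainIdx = as.integer(trainIdx), valIdx = as.integer(valIdx),
      testIdx = as.integer(fullSplit$testIdx),
      removedIdx = as.integer(intersect(c(fullSplit$trainIdx, fullSplit$valIdx),
                                        members)))
}

#' Maximum similarity of query molecules to a training subset
#'
#' For each query row, the maximum [pairwiseSimilarity()] against a seeded
#' random subset of the training molecules (the whole set if it has no
#' more than `subsetSize` rows).
#'
#' @param queryReps query representation matrix.
#' @param train training [MoleculeSet] (descriptor space) or a plain matrix.
#' @param subsetSize training subset size (default 1000).
#' @param seed subset-sampling seed.
#' @return numeric vector of similarities in \[0,1\].
#' @export
similarityToTraining <- function(queryReps, train, subsetSize = 1000, seed = 1) {
  trainReps <- if (is(train, "MoleculeSet")) descriptors(train) else train
  if (subsetSize < 1) stop("configuration error: empty subset", call. = FALSE)
  n <- nrow(trainReps)
  idx <- if (n > subsetSize)
    withSeed(derivedSeed(seed, "similarity-subset"), sample.int(n, subsetSize))
  else seq_len(n)
  sim01 <- (1 + cosineCross(queryReps, trainReps[idx, , drop = FALSE])) / 2
  apply(sim01, 1L, max)
}

#' Downsample a pool to a uniform similarity distribution
#'
#' Divides \[0,1\] into `nStrata` equal-width similarity strata and keeps an
#' equal (within one) number of molecules per stratum, emulating the
#' construction of an out-of-distribution evaluation pool whose
#' similarity-to-training scores are uniform over \[0,1\].
#'
#' @param pool an [OODPool].
#' @param nOut target number of molecules after downsampling.
#' @param nStrata number of similarity strata (default 10).
#' @param seed sampling seed.
#' @return an [OODPool] with ~`nOut` molecules, balanced across strata.
#' @export
uniformSimilaritySample <- function(pool, nOut, nStrata = 10, seed = 1) {
  stopifnot(is(pool, "OODPool"))
  s <- pool@similarity
  stratum <- pmin(pmax(ceiling(s * nStrata), 1L), nStrata)
  quota <- rep(nOut %/% nStrata, nStrata)
  rem <- nOut %% nStrata
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  counts <- tabulate(stratum, nStrata)
  short <- which(counts < quota)
  if (length(short))
    stop("infeasible sample: strata ", paste(short, collapse = ", "),
         " hold too few molecules for a uniform draw", call. = FALSE)
  keep <- withSeed(derivedSeed(seed, "uniform-downsample"), {
    unlist(lapply(seq_len(nStrata), function(k) {
      members <- which(stratum == k)
      members[sample.int(length(members), quota[k])]
    }))
  })
  keep <- sort(keep)
  new("OODPool", pool = pool@pool[keep], similarity = s[keep])
}

#' Butina-style sphere-exclusion clustering
#'
#' Repeatedly selects the unassigned molecule with the most unassigned
#' neighbours at similarity >= `threshold` as a cluster centroid, assigns
#' those neighbours to it, removes them, and repeats until everything is
#' assigned. Singletons are allowed; ties are broken by lowest index, so
#' the procedure is deterministic.
#'
#' @param similarityMatrix symmetric matrix with unit diagonal, values in
#'   \[0,1\].
#' @param threshold similarity threshold in (0,1).
#' @return integer cluster labels (1 = first/largest-seeded cluster).
#' @export
butinaClusters <- function(similarityMatrix, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0,1)", call. = FALSE)
  n <- nrow(similarityMatrix)
  if (!isTRUE(all.equal(similarityMatrix, t(similarityMatrix))))
    stop("input error: similarity matrix must be symmetric", call. = FALSE)
  adj <- similarityMatrix >= threshold
  diag(adj) <- FALSE
  labels <- integer(n)
  cl <- 0L
  unassigned <- rep(TRUE, n)
  while (any(unassigned)) {
    cand <- which(unassigned)
    nbrCount <- vapply(cand, function(i) sum(adj[i, ] & unassigned), integer(1))
    centroid <- cand[which.max(nbrCount)]  # which.max = lowest-index tie-break
    members <- c(centroid, which(adj[centroid, ] & unassigned))
    cl <- cl + 1L
    labels[members] <- cl
    unassigned[members] <- FALSE
  }
  labels
}

#' Mean pairwise distance within or between molecular groups
#'
#' Mean of the induced distance `2 * (1 - pairwiseSimilarity)` over all
#' unordered pairs within group A (`within = TRUE`) or over all A x B
#' pairs (`within = FALSE`). Values range from 0 (identical directions) to
#' 2 (antipodal).
#'
#' @param repsA,repsB representation matrices (rows = molecules); `repsB`
#'   ignored when `within = TRUE`.
#' @param within compute the within-A mean instead of A-vs-B.
#' @return scalar mean distance in \[0,2\].
#' @export
groupMeanDistance <- function(repsA, repsB = NULL, within = FALSE) {
  if (nrow(repsA) == 0L) stop("input error: empty group", call. = FALSE)
  if (within) {
    if (nrow(repsA) < 2L)
      stop("input error: within-group distance needs >= 2 molecules", call. = FALSE)
    sim <- (1 + cosineCross(repsA, repsA)) / 2
    d <- 2 * (1 - sim)
    mean(d[upper.tri(d)])
  } else {
    if (is.null(repsB) || nrow(repsB) == 0L)
      stop("input error: empty group", call. = FALSE)
    sim <- (1 + cosineCross(repsA, repsB)) / 2
    mean(2 * (1 - sim))
  }
}

#' Cluster coherence of each leave-bin-out scenario
#'
#' For every (component, bin) pair, the fraction of the bin's members that
#' belong to the bin's majority structural cluster. High-purity bins
#' correspond to the removal of a coherent structural region - the
#' situation the leave-bin-out construction is designed to emulate -
#' whereas low-purity bins merely slice through clusters.
#'
#' @param assignments list of [BinAssignment] from [pcaTopBins()].
#' @param cluster integer cluster labels for every molecule.
#' @return data.frame with columns `pcIndex`, `binIndex`, `purity`, sorted
#'   by decreasing purity.
#' @export
scenarioPurity <- function(assignments, cluster) {
  rows <- list()
  for (a in assignments) {
    for (b in seq_len(max(a@binOf))) {
      members <- cluster[a@binOf == b]
      rows[[length(rows) + 1L]] <- data.frame(
        pcIndex = a@pcIndex, binIndex = b,
        purity = max(tabulate(members)) / length(members))
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$purity), ]
}
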