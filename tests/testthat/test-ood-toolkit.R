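test_that("PCA percentile bins partition molecules into equal-count bins", {
  set.seed(21)
  X <- matrix(rnorm(100 * 6), 100)
  asn <- pcaTopBins(X, nComponents = 3, nBins = 5)
  expect_length(asn, 3L)
  for (a in asn) {
    expect_equal(unname(table(a@binOf)), rep(20L, 5L), ignore_attr = TRUE)
    expect_length(a@binEdges, 4L)
    expect_false(is.unsorted(a@binEdges))
  }
  # 3 components x 5 bins = the 15 leave-bin-out scenarios
  expect_equal(sum(vapply(asn, function(a) max(a@binOf), integer(1))), 15L)
  expect_error(pcaTopBins(matrix(1, 50, 4)), "degenerate")
})

test_that("rank binning keeps sizes within one even under heavy ties", {
  x <- c(rep(0, 37), rep(1, 40), rnorm(23))
  b <- molUQ:::rankBins(x, 5)
  sizes <- tabulate(b, 5)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(sizes), 100L)
  # brute-force: stable-sorted ranks split into 5 runs give the same sizes
  expect_equal(sort(sizes), sort(tabulate(ceiling(
    rank(x, ties.method = "first") * 5 / 100), 5)))
})

test_that("leaveBinOut excises the bin from train and val but not test", {
  set.seed(22)
  X <- matrix(rnorm(500 * 5), 500)
  asn <- pcaTopBins(X, 1, 5)[[1]]
  split <- randomSplit(500, c(0.7, 0.1, 0.2), seed = 1)
  lbo <- leaveBinOut(split, asn, 2)
  members <- which(asn@binOf == 2)
  expect_length(intersect(c(lbo@trainIdx, lbo@valIdx), members), 0L)
  expect_identical(lbo@testIdx, as.integer(split$testIdx))
  # train shrinks by about the bin share (20%)
  shrink <- 1 - length(lbo@trainIdx) / length(split$trainIdx)
  expect_gt(shrink, 0.1); expect_lt(shrink, 0.3)
  # re-adding the removed indices reconstitutes the original train+val
  expect_setequal(c(lbo@trainIdx, lbo@valIdx, lbo@removedIdx),
                  c(split$trainIdx, split$valIdx))
  expect_error(leaveBinOut(split, asn, 9), "out of range")
})

test_that("similarityToTraining takes the maximum over a seeded subset", {
  train <- angleVecs(c(0, pi / 3, pi / 2))
  # query equal to a training member
  expect_equal(similarityToTraining(angleVecs(0), train, seed = 1), 1)
  # query orthogonal to every member of a single-row training set
  expect_equal(similarityToTraining(matrix(c(0, 1), 1), matrix(c(1, 0), 1),
                                    seed = 1), 0.5)
  # enlarging the subset can never decrease any score
  set.seed(23)
  tr <- matrix(rnorm(200 * 4), 200)
  q <- matrix(rnorm(30 * 4), 30)
  sSmall <- similarityToTraining(q, tr, subsetSize = 50, seed = 9)
  sAll <- similarityToTraining(q, tr, subsetSize = 200, seed = 9)
  expect_true(all(sAll >= sSmall - 1e-12))
})

test_that("uniform similarity downsampling balances strata within one", {
  set.seed(24)
  n <- 2000
  X <- matrix(rnorm(n * 3), n)
  ms <- makeMS(X, rnorm(n))
  sim <- runif(n)
  pool <- new("OODPool", pool = ms, similarity = sim)
  out <- uniformSimilaritySample(pool, nOut = 100, nStrata = 10, seed = 2)
  expect_equal(nMolecules(out@pool), 100L)
  counts <- tabulate(pmin(pmax(ceiling(out@similarity * 10), 1L), 10L), 10)
  expect_lte(max(counts) - min(counts), 1L)
  # an empty stratum is reported by index
  simGap <- runif(n, 0.2, 1)  # stratum 1 (0-0.1) and 2 (0.1-0.2) empty
  poolGap <- new("OODPool", pool = ms, similarity = simGap)
  expect_error(uniformSimilaritySample(poolGap, 100, seed = 2),
               "strata 1, 2")
})

test_that("sphere-exclusion clustering handles degenerate graphs", {
  S1 <- matrix(1, 5, 5)
  expect_equal(butinaClusters(S1, 0.5), rep(1L, 5))
  S0 <- diag(5)
  expect_equal(butinaClusters(S0, 0.5), 1:5)  # all singletons
  expect_error(butinaClusters(S1, 0), "threshold")
  expect_error(butinaClusters(matrix(runif(16), 4), 0.5), "symmetric")
})

test_that("sphere-exclusion clustering matches a hand-crafted 6-item case", {
  # items 1-3 mutually similar, 4-5 similar, 6 isolated
  S <- diag(6)
  S[1, 2] <- S[1, 3] <- S[2, 3] <- 0.9
  S[4, 5] <- 0.8
  S <- pmax(S, t(S))
  lab <- butinaClusters(S, 0.7)
  expect_equal(lab, butinaBrute(S, 0.7))
  expect_length(unique(lab[1:3]), 1L)
  expect_length(unique(lab[4:5]), 1L)
  expect_false(lab[6] %in% lab[1:5])
})

test_that("sphere-exclusion clustering equals the exhaustive oracle on random instances", {
  for (s in 1:100) {
    set.seed(s)
    n <- 8
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    thr <- runif(1, 0.3, 0.7)
    expect_identical(butinaClusters(S, thr), butinaBrute(S, thr))
  }
})

test_that("group mean distance matches a brute-force double loop", {
  A <- angleVecs(c(0, 0))
  expect_equal(groupMeanDistance(A, within = TRUE), 0)
  pairAnti <- angleVecs(c(0, pi))
  expect_equal(groupMeanDistance(pairAnti, within = TRUE), 2, tolerance = 1e-12)
  set.seed(25)
  G1 <- matrix(rnorm(4 * 3), 4)
  G2 <- matrix(rnorm(5 * 3), 5)
  # brute within
  dsum <- 0; cnt <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    dsum <- dsum + 2 * (1 - pairwiseSimilarity(G1[i, ], G1[j, ])); cnt <- cnt + 1
  }
  expect_equal(groupMeanDistance(G1, within = TRUE), dsum / cnt,
               tolerance = 1e-12)
  # brute between
  dsum <- 0
  for (i in 1:4) for (j in 1:5)
    dsum <- dsum + 2 * (1 - pairwiseSimilarity(G1[i, ], G2[j, ]))
  expect_equal(groupMeanDistance(G1, G2), dsum / 20, tolerance = 1e-12)
  expect_error(groupMeanDistance(G1[0, , drop = FALSE]), "empty")
  expect_error(groupMeanDistance(G1[1, , drop = FALSE], within = TRUE), ">= 2")
})

test_that("scenario purity identifies cluster-coherent bins", {
  cfg <- syntheticConfig(nMolecules = 1000, seed = 2)
  ms <- generateDataset(cfg)
  asn <- pcaTopBins(descriptors(ms), 3, 5)
  pur <- scenarioPurity(asn, clusterLabels(ms))
  expect_equal(nrow(pur), 15L)
  expect_true(all(pur$purity >= 0.2 & pur$purity <= 1))
  expect_false(is.unsorted(rev(pur$purity)))
  # the best bin isolates essentially one cluster
  expect_gt(pur$purity[1], 0.9)
})
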