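test_that("quantile-interval uncertainty is half the interquantile width", {
  e <- gbmQuantileUQ(predLo = 1, predHi = 3, meanPred = 2)
  expect_equal(uqSigma(e), 1)
  expect_true(isCalibrated(e))
  expect_equal(uqSigma(gbmQuantileUQ(1, 1, 1)), 0)
  expect_warning(eX <- gbmQuantileUQ(1.2, 1.0, 1.1), "crossed")
  expect_equal(uqSigma(eX), 0)
  expect_error(gbmQuantileUQ(c(1, 2), 3, 2), "aligned")
})

test_that("ensemble aggregation uses the population standard deviation", {
  agg <- aggregateEnsemble(cbind(c(1, 5), c(3, 5)))
  expect_equal(uqMean(agg), c(2, 5))
  expect_equal(uqSigma(agg), c(1, 0))  # divide-by-M convention
  # identical members (same seed twice) collapse to zero spread
  v <- rnorm(10)
  expect_equal(uqSigma(aggregateEnsemble(cbind(v, v, v))), rep(0, 10))
  expect_error(aggregateEnsemble(matrix(1, 3, 1)), "at least 2")
})

test_that("seed-diverse ensembles give strictly positive uncertainty", {
  set.seed(11)
  X <- matrix(rnorm(400 * 4), 400)
  ms <- makeMS(X, rowSums(tanh(X)) + rnorm(400, sd = 0.3))
  spec <- regressorSpec(hiddenSizes = c(16, 8), dropoutRate = 0,
                        maxEpochs = 30, seed = 5)
  est <- ensembleUQ(spec, ms, NULL, matrix(rnorm(200 * 4), 200), M = 5)
  expect_gte(mean(uqSigma(est) > 0), 0.99)
  expect_error(ensembleUQ(spec, ms, NULL, X, M = 1), "M must be >= 2")
})

test_that("MC dropout collapses without stochasticity and is seed-stable", {
  set.seed(12)
  X <- matrix(rnorm(300 * 4), 300)
  ms <- makeMS(X, rowSums(X) + rnorm(300, sd = 0.2))
  m0 <- trainRegressor(regressorSpec(hiddenSizes = c(16, 8), dropoutRate = 0,
                                     maxEpochs = 20, seed = 2), ms,
                       head = "point")
  est0 <- mcdoUQ(m0, X[1:50, ], T = 10, seed = 4)
  expect_equal(uqSigma(est0), rep(0, 50))

  mD <- trainRegressor(regressorSpec(hiddenSizes = c(16, 8), dropoutRate = 0.3,
                                     maxEpochs = 20, seed = 2), ms,
                       head = "point")
  eA <- mcdoUQ(mD, X[1:50, ], T = 25, seed = 4)
  eB <- mcdoUQ(mD, X[1:50, ], T = 25, seed = 4)
  expect_identical(uqSigma(eA), uqSigma(eB))
  expect_gt(median(uqSigma(eA)), 0)
})

test_that("MC dropout sigma converges with the number of passes", {
  set.seed(13)
  X <- matrix(rnorm(300 * 4), 300)
  ms <- makeMS(X, rowSums(X) + rnorm(300, sd = 0.2))
  m <- trainRegressor(regressorSpec(hiddenSizes = c(16, 8), dropoutRate = 0.2,
                                    maxEpochs = 20, seed = 2), ms,
                      head = "point")
  Xq <- X[1:40, ]
  s500 <- uqSigma(mcdoUQ(m, Xq, T = 500, seed = 4))
  s1000 <- uqSigma(mcdoUQ(m, Xq, T = 1000, seed = 4))
  rel <- abs(s1000 - s500) / pmax(s500, 1e-12)
  expect_gte(mean(rel < 0.10), 0.95)
})

test_that("Gaussian negative log-likelihood matches its closed form", {
  expect_equal(mveNllLoss(0, 0, 1), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(mveNllLoss(1, 0, 1), 0.5 * log(2 * pi) + 0.5, tolerance = 1e-12)
  expect_equal(mveNllLoss(2, 2, exp(2)), 0.5 * log(2 * pi) + 1,
               tolerance = 1e-12)
  expect_error(mveNllLoss(0, 0, 0), "positive")
})

test_that("NIG density matches hand substitution, symmetry and quadrature", {
  # gamma=0, upsilon=1, alpha=2, beta=1 at (mu=0, sigma2=1)
  expect_equal(nigLogDensity(0, 1, 0, 1, 2, 1), -1 - 0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(exp(nigLogDensity(0, 1, 0, 1, 2, 1)), exp(-1) / sqrt(2 * pi),
               tolerance = 1e-12)
  # symmetric in mu about gamma
  expect_equal(nigLogDensity(1.7 + 0.4, 0.8, 1.7, 2, 3, 1.5),
               nigLogDensity(1.7 - 0.4, 0.8, 1.7, 2, 3, 1.5))
  # integrates to 1 over (mu, sigma2) for alpha = 3
  mu <- seq(-12, 12, length.out = 481)
  s2 <- seq(1e-4, 60, length.out = 3000)
  dens <- outer(mu, s2, function(m, s) exp(nigLogDensity(m, s, 0, 1, 3, 1)))
  integral <- sum(dens) * diff(mu[1:2]) * diff(s2[1:2])
  expect_lt(abs(integral - 1), 0.01)
  expect_error(nigLogDensity(0, 1, 0, -1, 2, 1), "domain")
  expect_error(nigLogDensity(0, 1, 0, 1, 0.5, 1), "domain")
})

test_that("NIG moments separate aleatoric and epistemic variance", {
  m <- nigMoments(2, 1, 3, 4)
  expect_equal(c(m$predMean, m$aleatoric, m$epistemic), c(2, 2, 2))
  m2 <- nigMoments(0.5, 4, 2, 1)
  expect_equal(c(m2$predMean, m2$aleatoric, m2$epistemic), c(0.5, 1, 0.25))
  # upsilon -> Inf: epistemic vanishes, aleatoric unchanged
  m3 <- nigMoments(0, 1e12, 3, 4)
  expect_equal(m3$aleatoric, 2)
  expect_lt(m3$epistemic, 1e-10)
  expect_error(nigMoments(0, 1, 1, 1), "alpha")
  expect_error(nigMoments(0, 0, 2, 1), "upsilon")
})

test_that("evidential components satisfy the total = aleatoric + epistemic identity", {
  set.seed(14)
  X <- matrix(rnorm(300 * 4), 300)
  ms <- makeMS(X, rowSums(tanh(X)) + rnorm(300, sd = 0.3))
  m <- trainRegressor(regressorSpec(hiddenSizes = c(16, 8), dropoutRate = 0,
                                    maxEpochs = 40, seed = 2),
                      ms, head = "evidential")
  Xq <- matrix(rnorm(100 * 4), 100)
  sT <- uqSigma(evidentialUQ(m, Xq, report = "total"))
  sA <- uqSigma(evidentialUQ(m, Xq, report = "aleatoric"))
  sE <- uqSigma(evidentialUQ(m, Xq, report = "epistemic"))
  expect_equal(sT^2, sA^2 + sE^2, tolerance = 1e-10)
  expect_error(evidentialUQ(m, Xq, report = "banana"))
  mp <- trainRegressor(regressorSpec(hiddenSizes = 8, maxEpochs = 3, seed = 1),
                       ms, head = "point")
  expect_error(evidentialUQ(mp, Xq), "unsupported model")
})

test_that("union approach couples neural features with quantile trees", {
  set.seed(15)
  cfg <- syntheticConfig(nMolecules = 1200, seed = 15)
  ms <- generateDataset(cfg)
  sp <- randomSplit(nMolecules(ms), c(0.7, 0.1, 0.2), seed = 15)
  m <- trainRegressor(regressorSpec(hiddenSizes = c(32, 16), dropoutRate = 0,
                                    maxEpochs = 60, learningRate = 3e-3,
                                    seed = 2),
                      ms[sp$trainIdx], ms[sp$valIdx], head = "point")
  est <- unionUQ(m, ms[sp$trainIdx], descriptors(ms[sp$testIdx]), seed = 1)
  expect_true(all(uqSigma(est) >= 0))
  expect_equal(uqMethod(est), "union")
  # means come from the neural model, not the trees
  expect_equal(uqMean(est),
               predictRegressor(m, descriptors(ms[sp$testIdx]))$mean)
  # uncertainty carries error signal on held-out molecules
  expect_gt(rhoError(est, targets(ms[sp$testIdx])), 0)
})

test_that("knn density uncertainty is the mean cosine distance to k neighbours", {
  q <- angleVecs(0)
  # train at angular cosine-distances 0.1, 0.2, 0.3, plus a far decoy
  train <- angleVecs(acos(1 - c(0.1, 0.2, 0.3, 0.9)))
  est <- knnDensityUQ(train, q, k = 3)
  expect_equal(uqSigma(est), 0.2, tolerance = 1e-12)
  expect_false(isCalibrated(est))
  # query duplicated in training: zero uncertainty
  dup <- knnDensityUQ(rbind(q, q, q), q, k = 3)
  expect_equal(uqSigma(dup), 0)
  # query orthogonal to all training rows: cosine distance 1
  orth <- knnDensityUQ(rbind(c(0, 1), c(0, 2), c(0, 3)), q, k = 3)
  expect_equal(uqSigma(orth), 1)
  expect_error(knnDensityUQ(q, q, k = 3), "fewer than k")
})

test_that("consensus averages aligned calibrated estimates", {
  e1 <- makeUQ(sigma = c(1, 4), mean = c(0, 1))
  e2 <- makeUQ(sigma = c(2, 5), mean = c(2, 1))
  e3 <- makeUQ(sigma = c(3, 6), mean = c(4, 1))
  cons <- consensusUQ(list(e1, e2, e3))
  expect_equal(uqSigma(cons), c(2, 5))
  expect_equal(uqMean(cons), c(2, 1))
  # idempotence on identical inputs
  same <- consensusUQ(list(e1, e1))
  expect_equal(uqSigma(same), uqSigma(e1))
  expect_equal(uqMean(same), uqMean(e1))
  bad <- makeUQ(sigma = c(1, 1))
  bad@ids <- c("x", "y")
  expect_error(consensusUQ(list(e1, bad)), "misaligned")
  dens <- makeUQ(sigma = c(1, 1), calibrated = FALSE)
  expect_error(consensusUQ(list(e1, dens)), "calibrated")
})

test_that("rank metrics are invariant to reporting sd versus variance", {
  set.seed(16)
  sigma <- runif(50, 0.1, 2)
  y <- rnorm(50)
  eSd <- makeUQ(sigma = sigma, mean = rep(0, 50))
  eVar <- makeUQ(sigma = sigma^2, mean = rep(0, 50))
  expect_equal(rhoError(eSd, y), rhoError(eVar, y), tolerance = 1e-12)
})
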