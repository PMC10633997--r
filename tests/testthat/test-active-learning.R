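test_that("uncertainty-weighted selection follows linear weighting", {
  w <- c(1, 1, 2)
  picks <- vapply(1:20000, function(s) selectBatch(w, 1, "uq_weighted",
                                                   seed = s), integer(1))
  freq <- tabulate(picks, 3) / length(picks)
  expect_lt(max(abs(freq - c(0.25, 0.25, 0.5))), 0.01)
  # goodness of fit against the linear weights
  expect_gt(stats::chisq.test(tabulate(picks, 3), p = w / sum(w))$p.value,
            0.01)
})

test_that("a dominant weight is selected almost surely", {
  w <- c(1000, rep(0.01, 5))
  picks <- vapply(1:2000, function(s) selectBatch(w, 1, "uq_weighted",
                                                  seed = s), integer(1))
  expect_gt(mean(picks == 1), 0.99)
})

test_that("selection handles exhaustion, caps and degenerate weights", {
  expect_setequal(selectBatch(runif(7), 7, "uq_weighted", seed = 1), 1:7)
  expect_setequal(selectBatch(runif(7), 7, "random", seed = 1), 1:7)
  expect_error(selectBatch(rep(0, 5), 2, "uq_weighted", seed = 1),
               "degenerate weights")
  expect_error(selectBatch(runif(3), 5, "random", seed = 1), "exceeds pool")
  meta <- list(oodFlags = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_warning(b <- selectBatch(runif(5), 4, "ood_only", meta, seed = 1),
                 "capped")
  expect_setequal(b, 1:2)
  b2 <- selectBatch(runif(5), 2, "ood_only", meta, seed = 1)
  expect_true(all(b2 %in% 1:2))
  expect_error(selectBatch(runif(4), 2, "diversity", list(), seed = 1),
               "diversity")
})

test_that("fractionOodSampled counts removed-bin membership", {
  expect_equal(fractionOodSampled(1:4, 9:12), 0)
  expect_equal(fractionOodSampled(9:12, 5:20), 1)
  expect_equal(fractionOodSampled(1:8, c(2, 4)), 0.25)
  expect_error(fractionOodSampled(integer(), 1:3), "empty batch")
})

test_that("improvement percentage follows the paired definition", {
  expect_equal(improvementPct(0.99, 1.00), 1.0, tolerance = 1e-12)
  expect_equal(improvementPct(c(1, 2), c(1, 2)), 0)
  expect_equal(improvementPct(c(0.9, 1.1), c(1, 1)), 0)
  expect_error(improvementPct(1, c(1, 2)), "paired")
  expect_error(improvementPct(1, 0), "degenerate")
})

test_that("paired one-sided t-test matches closed-form references", {
  # differences {0.1, 0.2, -0.3}: mean zero, t = 0, p = 0.5
  r <- pairedOneSidedT(rmseAl = c(0.9, 0.8, 1.3), rmseRandom = c(1, 1, 1))
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 0.5, tolerance = 1e-12)
  expect_false(r$degenerate)
  # constant nonzero differences: degenerate flag
  rd <- pairedOneSidedT(rep(0.9, 5), rep(1, 5))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p))
  # strong effect, closed-form t CDF check
  set.seed(41)
  d <- rnorm(30, mean = 0.1, sd = 0.02)
  al <- 1 - d; rnd <- rep(1, 30)
  r2 <- pairedOneSidedT(al, rnd)
  tref <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(r2$t, tref, tolerance = 1e-10)
  expect_equal(r2$p, pt(tref, df = 29, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(r2$p, 0.001)
  expect_error(pairedOneSidedT(1, 2), ">= 2")
})

test_that("the experiment grid enumerates the documented scenario counts", {
  g <- enumerateAlGrid()
  expect_equal(nrow(unique(g[c("initialFraction", "nAdd")])), 24L)
  expect_equal(nrow(unique(g[c("pcIndex", "binIndex")])), 15L)
  expect_equal(nrow(g), 360L)
})

test_that("grid summaries aggregate improvements and count configurations", {
  g <- enumerateAlGrid()
  g$sampler <- "uq_weighted"; g$subset <- "ood_bin"
  set.seed(42)
  g$improvementPct <- rnorm(nrow(g))
  s <- alGridSummary(g)
  expect_equal(unname(s$counts),
               c(24, 15, 360))
  expect_equal(nrow(s$byFraction), 4L)
  expect_equal(nrow(s$byNAdd), 6L)
  # single cell: summary equals that cell
  s1 <- alGridSummary(g[1, ])
  expect_equal(s1$byFraction$improvementPct, g$improvementPct[1])
  expect_error(alGridSummary(g[0, ]), "empty")
})

test_that("the AL experiment is paired, reproducible and accounted", {
  cfg <- syntheticConfig(nMolecules = 500, seed = 2)
  ms <- generateDataset(cfg)
  acfg <- alConfig(initialFraction = 0.2, nAdd = 30,
                   samplers = c("uq_weighted", "ood_only", "diversity"),
                   uqMethod = "knn_fp", scenario = "leave_bin_out",
                   pcIndex = 1, binIndex = 1, nReps = 2, seed = 5)
  out <- runAlExperiment(acfg, ms)
  # counting contract: reps x samplers (+ random) x 3 subsets
  expect_equal(nrow(out@reps), 2L * 4L * 3L)
  # ood_only samples only removed-bin molecules
  expect_equal(out@fracOod$fracOod[out@fracOod$sampler == "ood_only"],
               c(1, 1))
  # identical rerun: bitwise identical outcome (shared seeds throughout)
  out2 <- runAlExperiment(acfg, ms)
  expect_identical(out@reps, out2@reps)
  # random arm against itself: improvement exactly zero on every subset
  rndA <- out@reps$rmse[out@reps$sampler == "random"]
  rndB <- out2@reps$rmse[out2@reps$sampler == "random"]
  expect_equal(improvementPct(rndA, rndB), 0)
  # whole-test RMSE obeys the weighted mean-of-squares identity
  one <- out@reps[out@reps$rep == 1 & out@reps$sampler == "random", ]
  asn <- pcaTopBins(descriptors(ms), 3, 5)[[1]]
  split <- randomSplit(nMolecules(ms), c(0.8, 0, 0.2), seed = 5)
  nOod <- sum(asn@binOf[split$testIdx] == 1)
  nId <- length(split$testIdx) - nOod
  lhs <- one$rmse[one$subset == "whole"]^2 * (nOod + nId)
  rhs <- one$rmse[one$subset == "ood_bin"]^2 * nOod +
    one$rmse[one$subset == "id_bins"]^2 * nId
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("AL configuration validation rejects malformed settings", {
  expect_error(alConfig(initialFraction = 0), "initialFraction")
  expect_error(alConfig(nReps = 1), "nReps")
  expect_error(alConfig(samplers = "magic"), "unknown sampler")
})

test_that("AL-UQ correlation joins methods and matches brute force", {
  mt <- data.frame(uqMethod = c("a", "b", "c", "d"),
                   ence = c(0.1, 0.5, 0.9, 0.3),
                   rhoOod = c(0.9, 0.4, 0.1, 0.6))
  at <- data.frame(uqMethod = rep(c("a", "b", "c", "d"), 2),
                   subset = rep(c("ood_bin", "whole"), each = 4),
                   improvementPct = c(4, 2, 1, 3, 1, 2, 3, 4))
  M <- correlateAlWithUq(mt, at)
  imp <- c(4, 2, 1, 3)
  expect_equal(M["rhoOod", "ood_bin"], cor(mt$rhoOod, imp), tolerance = 1e-12)
  expect_equal(M["ence", "ood_bin"], cor(mt$ence, imp), tolerance = 1e-12)
  # a metric identical to the improvement column correlates exactly 1
  mt$direct <- imp
  expect_equal(correlateAlWithUq(mt, at)["direct", "ood_bin"], 1)
  # permuted pairings: null around zero
  set.seed(43)
  nulls <- replicate(100, {
    atp <- at
    atp$improvementPct[atp$subset == "ood_bin"] <- sample(imp)
    correlateAlWithUq(mt, atp)["rhoOod", "ood_bin"]
  })
  expect_lt(abs(mean(nulls)), 0.15)
  expect_error(correlateAlWithUq(mt[1:2, ], at), "insufficient")
})
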