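#' Configuration for the synthetic molecular dataset generator
#'
#' The generator emulates the structure of descriptor-based QSAR datasets:
#' molecules fall into structural clusters (Gaussian mixture in descriptor
#' space, inter-centre distance much larger than the within-cluster spread),
#' a lower-dimensional embedding block is a fixed seeded linear projection
#' of the descriptors plus 5% relative noise, and the target is a smooth
#' nonlinear function of the descriptors (a fixed seeded two-layer tanh
#' "teacher" network) observed under heteroscedastic Gaussian noise with
#' known per-molecule scale `sigma(x) = noiseBase + noiseHetero * g(x)`,
#' where `g` is a fixed logistic ramp along a seeded direction (values in
#' \[0,1\]).
#'
#' @param nMolecules number of molecules (rows).
#' @param nFeatures descriptor dimension p.
#' @param nEmbedding embedding dimension q (q << p).
#' @param nClusters number of structural clusters.
#' @param clusterSpread within-cluster coordinate sd.
#' @param noiseBase homoscedastic noise floor (target units).
#' @param noiseHetero amplitude of the heteroscedastic noise component.
#' @param oodDisplacement scale of the cluster-centre displacement used by
#'   [makeOodPool()]; multiples of this shift graded over \[0,1\] drive the
#'   similarity-to-training of pool molecules from in-distribution to far
#'   out-of-distribution.
#' @param seed integer seed; all generator randomness derives from it
#'   through named per-purpose streams.
#' @return a `SyntheticConfig` list.
#' @examples
#' cfg <- syntheticConfig(nMolecules = 200, seed = 1)
#' ms <- generateDataset(cfg)
#' ms
#' @export
syntheticConfig <- function(nMolecules = 2000, nFeatures = 32, nEmbedding = 8,
                            nClusters = 5, clusterSpread = 1,
                            noiseBase = 0.3, noiseHetero = 0.6,
                            oodDisplacement = 28, seed = 1) {
  if (nMolecules < 1 || nFeatures < 1 || nEmbedding < 1 || nClusters < 1)
    stop("configuration error: dimensions must be positive", call. = FALSE)
  if (nClusters > nMolecules)
    stop("configuration error: nClusters must not exceed nMolecules", call. = FALSE)
  if (clusterSpread <= 0)
    stop("configuration error: clusterSpread must be positive", call. = FALSE)
  if (noiseBase < 0 || noiseHetero < 0 || oodDisplacement < 0)
    stop("configuration error: scale parameters must be >= 0", call. = FALSE)
  structure(list(nMolecules = as.integer(nMolecules),
                 nFeatures = as.integer(nFeatures),
                 nEmbedding = as.integer(nEmbedding),
                 nClusters = as.integer(nClusters),
                 clusterSpread = clusterSpread, noiseBase = noiseBase,
                 noiseHetero = noiseHetero, oodDisplacement = oodDisplacement,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Deterministic structural parameters shared by generateDataset and
# makeOodPool: cluster centres, embedding projection, the teacher network
# and the heteroscedastic driver all depend only on (seed, dims).
teacherParams <- function(config) {
  p <- config$nFeatures
  withSeed(derivedSeed(config$seed, "teacher"), {
    h <- 16L
    u0 <- rnorm(p); u0 <- u0 / sqrt(sum(u0^2))
    # Cluster centres share a dominant direction (real descriptor and
    # fingerprint vectors occupy a cone, not the whole sphere) plus
    # per-cluster offsets much larger than the within-cluster spread.
    m0 <- 8 * config$clusterSpread * sqrt(p) * u0
    offsets <- matrix(rnorm(config$nClusters * p, sd = 3 * config$clusterSpread),
                      config$nClusters, p)
    list(
      u0 = u0, m0 = m0,
      centers = sweep(offsets, 2, m0, "+"),
      proj = matrix(rnorm(p * config$nEmbedding, sd = 1 / sqrt(p)),
                    p, config$nEmbedding),
      # sparse first layer: each hidden unit reads 2 descriptors, giving the
      # low-order feature interactions typical of engineered descriptors
      W1 = {
        W <- matrix(0, p, h)
        for (u in seq_len(h)) W[sample.int(p, 2L), u] <- rnorm(2L, sd = 0.25)
        W
      },
      b1 = rnorm(h, sd = 0.5),
      w2 = rnorm(h),
      b2 = rnorm(1, sd = 0.25),
      gDir = rnorm(p, sd = 1 / sqrt(p)),
      gOff = rnorm(1, sd = 0.25))
  })
}

# The smooth nonlinear structure->property teacher f(X), evaluated on
# coordinates centred at the shared cluster offset.
teacherValues <- function(params, X) {
  Xc <- sweep(X, 2, params$m0, "-")
  drop(tanh(Xc %*% params$W1 + matrix(params$b1, nrow(Xc), length(params$b1),
                                      byrow = TRUE)) %*% params$w2) + params$b2
}

# Heteroscedastic driver g(x) in [0,1]: logistic ramp along a fixed
# direction of the centred coordinates.
heteroDriver <- function(params, X) {
  sigmoid(drop(sweep(X, 2, params$m0, "-") %*% params$gDir) + params$gOff)
}

# sigma_true(x) = noiseBase + noiseHetero * g(x)
noiseScale <- function(config, params, X) {
  config$noiseBase + config$noiseHetero * heteroDriver(params, X)
}

buildMoleculeSet <- function(config, params, X, cluster, idPrefix, noiseSeed) {
  n <- nrow(X)
  E <- X %*% params$proj
  withSeed(derivedSeed(noiseSeed, "embedding-noise"), {
    relSd <- 0.05 * apply(E, 2, sd)
    relSd[relSd == 0] <- 0.05
    E <- E + matrix(rnorm(n * ncol(E)), n) %*% diag(relSd, ncol(E))
  })
  f <- teacherValues(params, X)
  st <- noiseScale(config, params, X)
  y <- withSeed(derivedSeed(noiseSeed, "target-noise"),
                f + rnorm(n) * st)
  new("MoleculeSet",
      ids = sprintf("%s%06d", idPrefix, seq_len(n)),
      X = X, E = E, y = y, cluster = as.integer(cluster), sigmaTrue = st)
}

#' Generate a clustered synthetic molecular regression dataset
#'
#' Draws descriptors from a mixture of `nClusters` Gaussian clusters whose
#' centres are far apart relative to the within-cluster spread (so that PCA
#' percentile bins correspond to structural regions), builds embeddings as
#' a seeded linear projection of the descriptors plus small relative noise,
#' and produces targets `y = f(X) + eps` from the fixed nonlinear teacher
#' with `eps ~ N(0, sigmaTrue(x)^2)`. Bit-identical output for identical
#' configurations.
#'
#' @param config a [syntheticConfig()].
#' @return a [MoleculeSet] with known `sigmaTrue`.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  params <- teacherParams(config)
  n <- config$nMolecules
  X <- withSeed(derivedSeed(config$seed, "data"), {
    cluster <- sample(rep_len(seq_len(config$nClusters), n))
    params$centers[cluster, , drop = FALSE] +
      matrix(rnorm(n * config$nFeatures, sd = config$clusterSpread), n)
  })
  cluster <- withSeed(derivedSeed(config$seed, "data"),
                      sample(rep_len(seq_len(config$nClusters), n)))
  buildMoleculeSet(config, params, X, cluster, "MOL", config$seed)
}

#' Bounded pairwise similarity between two feature vectors
#'
#' Maps cosine similarity from \[-1,1\] to \[0,1\] via `(1 + cos)/2`, the
#' synthetic analogue of a fingerprint similarity: 1 for positively
#' proportional vectors, 0 for antipodal ones. The induced distance
#' `2 * (1 - similarity)` spans \[0,2\].
#'
#' @param a,b equal-length numeric vectors, neither all-zero.
#' @return similarity in \[0,1\].
#' @examples
#' pairwiseSimilarity(c(1, 0), c(0, 1))  # 0.5
#' @export
pairwiseSimilarity <- function(a, b) {
  if (length(a) != length(b))
    stop("input error: vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero vector has no direction", call. = FALSE)
  (1 + sum(a * b) / (na * nb)) / 2
}

#' Generate a candidate pool spanning in- to out-of-distribution molecules
#'
#' Pool molecules are drawn around the training cluster centres displaced by
#' graded multiples (uniform in \[0,1\]) of `oodDisplacement` along random
#' directions, so maximum-similarity-to-training scores span a wide range.
#' Targets still come from the same teacher, so pool labels are usable for
#' active-learning augmentation.
#'
#' @param config the [syntheticConfig()] that generated the training data.
#' @param train the training [MoleculeSet] (provides the reference frame;
#'   the teacher is reconstructed from `config`).
#' @param nPool number of pool molecules.
#' @param seed optional seed; defaults to a stream derived from the config
#'   seed.
#' @param levelRange displacement levels are drawn uniformly from this
#'   subinterval of \[0,1\]; `c(0.8, 1)` yields a strongly displaced
#'   cluster, `c(0, 0)` an in-distribution pool.
#' @return a [MoleculeSet]; cluster labels record the parent cluster.
#' @export
makeOodPool <- function(config, train, nPool, seed = NULL,
                        levelRange = c(0, 1)) {
  stopifnot(inherits(config, "SyntheticConfig"), is(train, "MoleculeSet"))
  if (nPool <= 0)
    stop("configuration error: nPool must be positive", call. = FALSE)
  params <- teacherParams(config)
  poolSeed <- if (is.null(seed)) derivedSeed(config$seed, "ood-pool")
              else as.integer(seed)
  p <- config$nFeatures
  X <- withSeed(poolSeed, {
    cluster <- sample(config$nClusters, nPool, replace = TRUE)
    level <- runif(nPool, levelRange[1], levelRange[2])
    # graded shift against the shared cone direction: level 0 stays
    # in-distribution, level 1 reaches (beyond) the antipodal region, so
    # maximum similarity to training sweeps from ~1 down towards 0
    shift <- -outer(level * config$oodDisplacement * config$clusterSpread *
                      sqrt(p), params$u0)
    tang <- matrix(rnorm(nPool * p, sd = config$clusterSpread), nPool)
    params$centers[cluster, , drop = FALSE] + tang + shift
  })
  cluster <- withSeed(poolSeed, sample(config$nClusters, nPool, replace = TRUE))
  buildMoleculeSet(config, params, X, cluster, "POOL", poolSeed)
}
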