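#' @importFrom stats cor dist predict prcomp quantile rnorm runif sd setNames
#'   t.test pt
#' @importFrom methods new validObject is slot
#' @importFrom utils head read.csv write.csv
NULL

# Named per-purpose seed streams. All randomness in the package flows through
# withSeed(derivedSeed(seed, purpose), ...), so paired experimental arms can
# share exactly the streams they must share and no others.
derivedSeed <- function(seed, purpose) {
  stopifnot(is.character(purpose), length(purpose) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Numerically stable softplus and its derivative (the logistic sigmoid).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-normalize to unit L2 norm; zero rows are an error for cosine work.
unitRows <- function(m, what = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("undefined similarity: zero ", what, " has no direction", call. = FALSE)
  m / nrm
}

# Cosine similarity between rows of a and rows of b (n_a x n_b).
cosineCross <- function(a, b) {
  tcrossprod(unitRows(a, "row"), unitRows(b, "row"))
}

# Population (divide-by-n) standard deviation over matrix rows.
rowPopSd <- function(m) {
  mu <- rowMeans(m)
  v <- rowMeans(m^2) - mu^2
  v[v < 0] <- 0
  sqrt(v)
}

# Equal-count binning by rank with a stable first-index tie-break.
# Guarantees bin sizes differ by at most one even under heavy ties.
rankBins <- function(x, nBins) {
  n <- length(x)
  if (n < nBins) stop("fewer observations than bins", call. = FALSE)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * nBins / n))
}

# z-scoring with stored training statistics; constant columns get sd 1.
fitScaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}
applyScaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
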