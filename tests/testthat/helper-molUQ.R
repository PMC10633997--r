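# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal MoleculeSet from raw matrices.
makeMS <- function(X, y, E = NULL, cluster = NULL, sigmaTrue = NULL,
                   ids = NULL) {
  n <- nrow(X)
  if (is.null(E)) E <- matrix(0, n, 1)
  if (is.null(cluster)) cluster <- rep(1L, n)
  if (is.null(sigmaTrue)) sigmaTrue <- rep(NA_real_, n)
  if (is.null(ids)) ids <- sprintf("m%06d", seq_len(n))
  new("MoleculeSet", ids = ids, X = X, E = E, y = y,
      cluster = as.integer(cluster), sigmaTrue = sigmaTrue)
}

# A UQEstimate straight from vectors.
makeUQ <- function(sigma, mean = rep(0, length(sigma)), calibrated = TRUE,
                   method = "test") {
  new("UQEstimate", ids = sprintf("m%06d", seq_along(sigma)),
      mean = mean, sigma = sigma, calibrated = calibrated, method = method)
}

# Unit vectors at given angles (2D), handy for exact cosine geometry.
angleVecs <- function(theta) cbind(cos(theta), sin(theta))

# Brute-force Spearman: explicit average ranks + Pearson sum formula.
spearmanBrute <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Brute-force sphere-exclusion clustering, written independently of the
# package implementation (explicit loops, no shared helpers).
butinaBrute <- function(S, thr) {
  n <- nrow(S)
  lab <- integer(n)
  k <- 0L
  repeat {
    un <- which(lab == 0L)
    if (!length(un)) break
    best <- -1L; cen <- NA_integer_
    for (i in un) {
      cnt <- 0L
      for (j in un) if (j != i && S[i, j] >= thr) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; cen <- i }
    }
    k <- k + 1L
    lab[cen] <- k
    for (j in un) if (j != cen && S[cen, j] >= thr) lab[j] <- k
  }
  lab
}
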