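# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms and
# direct per-element arithmetic only.

# Exhaustive active-set NNLS oracle: solve unconstrained least squares on
# every subset of endmembers, keep the feasible (all-nonnegative) solution
# with the smallest residual.
nnlsSubsetOracle <- function(A, x) {
  m <- ncol(A)
  best <- rep(0, m)
  bestRes <- sum(x^2)
  for (k in seq_len(2^m) - 1L) {
    sel <- as.logical(bitwAnd(k, 2^(seq_len(m) - 1L)))
    if (!any(sel)) next
    cf <- tryCatch(qr.coef(qr(A[, sel, drop = FALSE]), x),
                   error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf)) || any(cf < -1e-10)) next
    res <- sum((x - A[, sel, drop = FALSE] %*% cf)^2)
    if (res < bestRes - 1e-12) {
      bestRes <- res
      best <- rep(0, m)
      best[sel] <- pmax(cf, 0)
    }
  }
  best
}

# Brute-force Otsu: maximize between-class variance over every candidate
# bin edge of an nBins histogram on [min, max].
otsuOracle <- function(v, nBins = 256L) {
  edges <- seq(min(v), max(v), length.out = nBins + 1L)
  bestSigma <- -Inf
  bestEdge <- NA_real_
  n <- length(v)
  mids <- (edges[-1] + edges[-(nBins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              nBins)
  for (k in seq_len(nBins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0)
    if (n0 == 0 || n0 == n) next
    mu0 <- mean(mids[bin[in0]])
    mu1 <- mean(mids[bin[!in0]])
    sigma <- (n0 / n) * ((n - n0) / n) * (mu0 - mu1)^2
    if (sigma > bestSigma + 1e-15) {
      bestSigma <- sigma
      bestEdge <- edges[k + 1L]
    }
  }
  bestEdge
}

# Closed-form inverse of a 2x2 or 3x3 matrix by cofactor expansion.
cofactorInverse <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(matrix(1 / M[1, 1], 1, 1))
  if (n == 2L) {
    d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    return(matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / d)
  }
  stopifnot(n == 3L)
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    sub <- M[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) *
      (sub[1, 1] * sub[2, 2] - sub[1, 2] * sub[2, 1])
  }
  d <- sum(M[1, ] * cof[1, ])
  t(cof) / d
}

# Build a random corrected stack from an explicit pixel-spectrum matrix.
stackFromPixels <- function(X, shape, wavelengths) {
  spectralStack(array(X, c(nrow(X), shape)), wavelengths, corrected = TRUE)
}

# A small random nonnegative stack for generic I/O and detector tests.
randomStack <- function(seed, bands = 5L, shape = c(6L, 7L),
                        wavelengths = seq(400, by = 10,
                                          length.out = bands)) {
  set.seed(seed)
  d <- array(runif(bands * prod(shape), 0, 100), c(bands, shape))
  spectralStack(d, wavelengths, corrected = TRUE)
}
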