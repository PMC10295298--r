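# Non-negative least squares, Lawson-Hanson active-set method, batched over
# many right-hand sides (pixels). All pixels iterate in lockstep; the
# unconstrained subproblems are grouped by passive-set pattern so each
# distinct pattern costs one small linear solve regardless of pixel count.
#
# A: B x m design matrix (endmember spectra as columns), X: B x N pixel
# matrix. Returns the m x N coefficient matrix minimizing ||x - A a||_2
# subject to a >= 0, per column. Ties in the active-set selection are
# broken toward the lowest endmember index.
nnlsBatch <- function(A, X) {
  B <- nrow(A)
  m <- ncol(A)
  N <- ncol(X)
  stopIfNot(m >= 1L && all(is.finite(A)) && any(A != 0),
            "unmixing requires a library of rank >= 1")
  AtA <- crossprod(A)
  AtX <- crossprod(A, X)                       # m x N
  coef <- matrix(0, m, N)
  passive <- matrix(FALSE, m, N)
  gradTol <- 1e-10 * pmax(1, apply(abs(AtX), 2L, max))
  pow2 <- 2^(seq_len(m) - 1L)

  solveGroups <- function(cols) {
    s <- matrix(0, m, length(cols))
    key <- as.vector(pow2 %*% passive[, cols, drop = FALSE])
    for (k in unique(key)) {
      if (k == 0) next
      idx <- which(key == k)
      P <- passive[, cols[idx[1L]]]
      G <- AtA[P, P, drop = FALSE]
      rhs <- AtX[P, cols[idx], drop = FALSE]
      sol <- tryCatch(solve(G, rhs), error = function(e) {
        # rank-deficient passive set: minimum-norm solution via SVD
        sv <- svd(G)
        pos <- sv$d > max(sv$d) * 1e-12
        sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
      })
      s[P, idx] <- sol
    }
    s
  }

  todo <- seq_len(N)
  outer <- 0L
  while (length(todo) && outer < 30L * m) {
    outer <- outer + 1L
    W <- AtX[, todo, drop = FALSE] - AtA %*% coef[, todo, drop = FALSE]
    W[passive[, todo, drop = FALSE]] <- -Inf
    live <- apply(W, 2L, max) > gradTol[todo] &
      colSums(passive[, todo, drop = FALSE]) < m
    todo <- todo[live]
    if (!length(todo)) break
    j <- apply(W[, live, drop = FALSE], 2L, which.max)  # first max = lowest index
    passive[cbind(j, todo)] <- TRUE

    work <- todo
    inner <- 0L
    while (length(work) && inner <= m + 1L) {
      inner <- inner + 1L
      s <- solveGroups(work)
      sP <- s
      sP[!passive[, work, drop = FALSE]] <- Inf
      bad <- apply(sP, 2L, min) <= 0
      if (any(!bad))
        coef[, work[!bad]] <- pmax(s[, !bad, drop = FALSE], 0)
      work <- work[bad]
      if (!length(work)) break
      # feasibility step: move toward s until the first passive variable
      # hits zero, then release it from the passive set
      cc <- coef[, work, drop = FALSE]
      ss <- s[, bad, drop = FALSE]
      step <- passive[, work, drop = FALSE] & ss <= 0
      ratio <- cc / (cc - ss)
      ratio[!step] <- Inf
      alpha <- apply(ratio, 2L, min)
      cc <- cc + rep(alpha, each = m) * (ss - cc)
      release <- passive[, work, drop = FALSE] & cc <= 1e-11
      cc[release] <- 0
      coef[, work] <- pmax(cc, 0)
      passive[, work] <- passive[, work, drop = FALSE] & !release
    }
  }
  coef
}
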