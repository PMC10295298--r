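makeLib <- function(S, wl = seq(400, by = 10, length.out = ncol(S))) {
  rownames(S) <- paste0("e", seq_len(nrow(S)))
  assembleLibrary(S, wl)
}

test_that("LU recovers exact mixtures and respects nonnegativity", {
  wl <- c(400, 410, 420, 430)
  S <- rbind(c(1, 0.5, 0.2, 0.1), c(0.1, 0.4, 0.8, 1))
  lib <- makeLib(S, wl)
  r1 <- getSpectrum(lib, "e1"); r2 <- getSpectrum(lib, "e2")

  st <- stackFromPixels(cbind(2 * r1 + 3 * r2), c(1L, 1L), wl)
  res <- unmixLU(st, lib)
  expect_equal(mapValues(res@maps[["e1"]])[1, 1], 2, tolerance = 1e-9)
  expect_equal(mapValues(res@maps[["e2"]])[1, 1], 3, tolerance = 1e-9)
  expect_equal(res@rmsError[1, 1], 0, tolerance = 1e-9)

  # a negated target cannot produce negative abundance
  neg <- spectralStack(array(pmax(-r1, 0), c(4, 1, 1)), wl,
                       corrected = TRUE)
  resn <- unmixLU(stackFromPixels(cbind(r2 * 0), c(1L, 1L), wl), lib)
  expect_equal(mapValues(resn@maps[["e1"]])[1, 1], 0)
  expect_true(all(mapValues(res@maps[["e1"]]) >= 0))
})

test_that("LU matches the exhaustive subset-enumeration NNLS oracle", {
  set.seed(101)
  B <- 5L; m <- 3L; n <- 300L
  A <- matrix(runif(B * m), B, m)
  A <- sweep(A, 2, apply(A, 2, max), "/")
  lib <- makeLib(t(A))
  X <- matrix(rnorm(B * n, 5, 4), B, n)
  X <- pmax(X, 0)
  st <- stackFromPixels(X, c(15L, 20L), wavelengths(lib))
  res <- unmixLU(st, lib)
  est <- rbind(as.vector(mapValues(res@maps[[1]])),
               as.vector(mapValues(res@maps[[2]])),
               as.vector(mapValues(res@maps[[3]])))
  for (j in seq_len(n))
    expect_equal(est[, j], nnlsSubsetOracle(A, X[, j]),
                 tolerance = 1e-6)
})

test_that("LU agrees with an independent active-set implementation", {
  skip_if_not_installed("pracma")
  set.seed(55)
  B <- 8L; m <- 4L
  A <- matrix(runif(B * m), B, m)
  A <- sweep(A, 2, apply(A, 2, max), "/")
  lib <- makeLib(t(A), seq(360, by = 5, length.out = B))
  X <- pmax(matrix(rnorm(B * 50, 3, 5), B, 50), 0)
  st <- stackFromPixels(X, c(5L, 10L), wavelengths(lib))
  res <- unmixLU(st, lib)
  for (j in seq_len(50)) {
    ref <- pracma::lsqnonneg(A, X[, j])$x
    got <- vapply(res@maps, function(mp) as.vector(mapValues(mp))[j], 0)
    expect_equal(unname(got), unname(ref), tolerance = 1e-6)
  }
})

test_that("SAM reproduces textbook angles and conventions", {
  wl <- c(400, 410)
  st <- stackFromPixels(cbind(c(3, 3), c(0, 1), c(1, 1), c(0, 0)),
                        c(2L, 2L), wl)
  m <- samAngle(st, c(1, 0))
  v <- as.vector(mapValues(m))
  expect_equal(v[1], pi / 4)         # (1,1)-direction pixel vs (1,0)
  expect_equal(v[2], pi / 2)         # orthogonal
  expect_equal(v[3], pi / 4)
  expect_equal(v[4], pi / 2)         # zero-norm pixel convention
  expect_equal(m@positiveDirection, "less")

  # collinear pixel at any positive scale has angle 0
  st2 <- stackFromPixels(cbind(c(2, 4) * 7.3), c(1L, 1L), wl)
  expect_equal(as.vector(mapValues(samAngle(st2, c(2, 4)))), 0,
               tolerance = 1e-7)
  expect_error(samAngle(st, c(0, 0)), "zero target")
})

test_that("SAM is scale-invariant and symmetric", {
  set.seed(19)
  wl <- seq(400, 440, 10)
  x <- runif(5); r <- runif(5)
  base <- as.vector(mapValues(samAngle(
    stackFromPixels(cbind(x), c(1L, 1L), wl), r)))
  for (c_ in c(1e-3, 0.5, 40)) {
    expect_equal(as.vector(mapValues(samAngle(
      stackFromPixels(cbind(c_ * x), c(1L, 1L), wl), r))), base,
      tolerance = 1e-9)
    expect_equal(as.vector(mapValues(samAngle(
      stackFromPixels(cbind(x), c(1L, 1L), wl), c_ * r))), base,
      tolerance = 1e-9)
  }
  swapped <- as.vector(mapValues(samAngle(
    stackFromPixels(cbind(r), c(1L, 1L), wl), x)))
  expect_equal(swapped, base, tolerance = 1e-12)
})

test_that("CEM satisfies the unity-gain constraint and scores a pure
           target image at 1", {
  st <- randomStack(42, bands = 6L, shape = c(8L, 8L))
  set.seed(43)
  r <- runif(6, 0.1, 1)
  f <- cemBuild(st, r)
  expect_lt(abs(sum(f@operator * r) - 1), 1e-9)

  pure <- stackFromPixels(matrix(r, 6, 12), c(3L, 4L), wavelengths(st))
  fp <- cemBuild(pure, r)
  expect_equal(as.vector(mapValues(cemApply(fp, pure))), rep(1, 12),
               tolerance = 1e-6)
})

test_that("CEM matches closed-form 2x2 matrix algebra", {
  wl <- c(400, 410)
  set.seed(23)
  X <- matrix(runif(8, 0.5, 3), 2, 4)
  st <- stackFromPixels(X, c(2L, 2L), wl)
  r <- c(1, 0)
  f <- cemBuild(st, r)
  R <- (X %*% t(X)) / 4                     # hand-formed correlation
  Rinv <- cofactorInverse(R)
  L <- (Rinv %*% r) / as.numeric(t(r) %*% Rinv %*% r)
  expect_equal(f@operator, as.vector(L), tolerance = 1e-9)
  expect_equal(as.vector(mapValues(cemApply(f, st))),
               as.vector(t(L) %*% X), tolerance = 1e-9)
})

test_that("MF reproduces the coordinate-projection example", {
  wl <- c(400, 410, 420)
  S <- rbind(c(1, 1, 0), c(1, 0, 0))      # target e1, background e2
  lib <- makeLib(S, wl)
  op <- mfBuild(lib, "e1")
  expect_equal(op@rejection, diag(c(0, 1, 1)), tolerance = 1e-12)
  expect_equal(op@filterVector, c(0, 1, 0), tolerance = 1e-12)
  st <- stackFromPixels(cbind(c(3, 4, 5)), c(1L, 1L), wl)
  expect_equal(as.vector(mapValues(mfApply(op, st))), 4,
               tolerance = 1e-12)
  # a background spectrum is annihilated
  bg <- stackFromPixels(cbind(c(1, 0, 0) * 9), c(1L, 1L), wl)
  expect_equal(as.vector(mapValues(mfApply(op, bg))), 0,
               tolerance = 1e-9)
})

test_that("MF projector matches an explicit cofactor-inversion oracle on
           random libraries", {
  set.seed(61)
  for (rep in 1:5) {
    B <- 6L
    S <- matrix(runif(4 * B, 0.05, 1), 4, B)
    S <- sweep(S, 1, apply(S, 1, max), "/")
    lib <- makeLib(S, seq(400, by = 8, length.out = B))
    op <- mfBuild(lib, "e2")
    U <- t(S[-2, , drop = FALSE])
    G <- t(U) %*% U
    P <- diag(B) - U %*% cofactorInverse(G) %*% t(U)
    expect_equal(op@rejection, P, tolerance = 1e-9)
    expect_equal(op@filterVector, as.vector(S[2, ] %*% P),
                 tolerance = 1e-9)
    # projector algebra
    expect_lt(max(abs(op@rejection %*% op@rejection - op@rejection)),
              1e-9)
    expect_lt(max(abs(op@rejection %*% U)), 1e-9)
  }
})

test_that("normalized MF scores a pure unit-abundance target pixel at 1", {
  lib <- makeLibrary(exampleModels(), seq(360, 480, 5))
  op <- mfBuild(lib, "Cal520", normalized = TRUE)
  st <- stackFromPixels(cbind(getSpectrum(lib, "Cal520")), c(1L, 1L),
                        wavelengths(lib))
  expect_equal(as.vector(mapValues(mfApply(op, st))), 1,
               tolerance = 1e-9)
})

test_that("LU and MF respond linearly to added target signal; SAM does
           not", {
  set.seed(29)
  wl <- seq(360, 480, 5)
  lib <- makeLibrary(exampleModels(), wl)
  r <- getSpectrum(lib, "Cal520")
  # strictly positive mixtures keep the nonnegativity constraint inactive,
  # the regime in which LU is an affine map of the pixel spectrum
  A0 <- matrix(runif(3 * 9, 2, 10), 3, 9)
  X0 <- t(spectraMatrix(lib)) %*% A0
  mk <- function(X) stackFromPixels(X, c(3L, 3L), wl)
  aVals <- c(1, 2.5, 7)
  op <- mfBuild(lib, "Cal520")
  base <- list(
    LU = mapValues(unmixLU(mk(X0), lib)@maps[["Cal520"]]),
    MF = mapValues(mfApply(op, mk(X0))))
  for (a in aVals) {
    Xa <- X0 + a * r
    dLU <- mapValues(unmixLU(mk(Xa), lib)@maps[["Cal520"]]) - base$LU
    dMF <- mapValues(mfApply(op, mk(Xa))) - base$MF
    # the increment is the same at every pixel and proportional to a
    expect_lt(diff(range(dLU)), 1e-6)
    expect_equal(mean(dLU), a, tolerance = 1e-6)
    expect_lt(diff(range(dMF)), 1e-9)
    expect_equal(mean(dMF) / sum(op@filterVector * r), a,
                 tolerance = 1e-9)
  }
  sam0 <- mapValues(samAngle(mk(X0), r))
  dSAM1 <- mapValues(samAngle(mk(X0 + 1 * r), r)) - sam0
  dSAM7 <- mapValues(samAngle(mk(X0 + 7 * r), r)) - sam0
  expect_gt(diff(range(dSAM1)), 1e-4)      # increment varies by pixel
  expect_gt(max(abs(dSAM7 - 7 * dSAM1)), 1e-3)  # and is not linear in a
})

test_that("degenerate detector inputs raise conditioning errors", {
  wl <- c(400, 410, 420)
  S <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))  # e1 == e2
  lib <- makeLib(S, wl)
  expect_error(mfBuild(lib, "e3"), "linearly dependent")
  expect_error(applyDetector(randomStack(1, bands = 3L,
                                         wavelengths = wl),
                             lib, "nope", "MF"), "target")
})
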