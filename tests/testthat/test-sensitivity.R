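injLib <- function() makeLibrary(exampleModels(), seq(360, 480, 5))

test_that("injectTarget adds a*r inside the ROI and nothing outside", {
  lib <- injLib()
  st <- randomStack(3, bands = 25L, shape = c(6L, 6L),
                    wavelengths = wavelengths(lib))
  roi <- matrix(FALSE, 6, 6); roi[2:4, 3:5] <- TRUE
  r <- getSpectrum(lib, "Cal520")

  expect_identical(stackData(injectTarget(st, roi, r, 0)), stackData(st))

  zero <- spectralStack(array(0, c(25, 6, 6)), wavelengths(lib),
                        corrected = TRUE)
  inj7 <- injectTarget(zero, roi, r, 7)
  expect_equal(stackData(inj7)[, 3, 4], unname(7 * r))
  expect_true(all(stackData(inj7)[, 1, 1] == 0))

  inj3 <- injectTarget(st, roi, r, 3)
  diffArr <- stackData(inj3) - stackData(st)
  for (i in 1:6) for (j in 1:6) {
    expected <- if (roi[i, j]) 3 * r else rep(0, 25)
    expect_equal(unname(diffArr[, i, j]), unname(expected),
                 tolerance = 1e-12)
  }
  expect_error(injectTarget(st, roi, r, -1), ">= 0")
})

test_that("LU sensitivity curve on a zero background recovers the
           injection exactly", {
  lib <- injLib()
  zero <- spectralStack(array(0, c(25, 8, 8)), wavelengths(lib),
                        corrected = TRUE)
  roi <- matrix(FALSE, 8, 8); roi[3:6, 3:6] <- TRUE
  cfg <- tsaConfig(roi, "Cal520", "LU", aGrid = 0:5)
  ts <- runTSC(zero, cfg, lib)
  expect_equal(ts$tsc$mean, 0:5, tolerance = 1e-9)
  expect_equal(unname(ts$fit[["slope"]]), 1, tolerance = 1e-9)
  expect_equal(unname(ts$fit[["r2"]]), 1, tolerance = 1e-9)
})

test_that("SAM angle decreases monotonically as target is injected over an
           AF background", {
  lib <- injLib()
  af <- getSpectrum(lib, "AF")
  st <- stackFromPixels(matrix(af * 20, 25, 16), c(4L, 4L),
                        wavelengths(lib))
  roi <- matrix(TRUE, 4, 4)
  cfg <- tsaConfig(roi, "Cal520", "SAM", aGrid = 0:25)
  ts <- runTSC(st, cfg, lib)
  expect_true(all(diff(ts$tsc$mean) < 0))
  # and the angle tends to 0 in the large-injection limit
  big <- injectTarget(st, roi, "Cal520", 1e6, lib)
  expect_lt(max(mapValues(samAngle(big, "Cal520", lib))), 1e-2)
})

test_that("MF sensitivity slope equals the hand-computed q.r gain", {
  lib <- injLib()
  af <- getSpectrum(lib, "AF")
  st <- stackFromPixels(matrix(af * 15, 25, 36), c(6L, 6L),
                        wavelengths(lib))
  roi <- matrix(FALSE, 6, 6); roi[2:5, 2:5] <- TRUE
  cfg <- tsaConfig(roi, "Cal520", "MF", aGrid = 0:10)
  ts <- runTSC(st, cfg, lib)
  S <- spectraMatrix(lib)
  U <- t(S[c("NucBlue", "AF"), ])
  P <- diag(25) - U %*% solve(t(U) %*% U) %*% t(U)
  q <- as.vector(S["Cal520", ] %*% P)
  expect_equal(unname(ts$fit[["slope"]]), sum(q * S["Cal520", ]),
               tolerance = 1e-9)
  expect_equal(unname(ts$fit[["r2"]]), 1, tolerance = 1e-12)
})

test_that("the positive-pixel curve steps at the detection threshold on a
           noiseless zero background", {
  lib <- injLib()
  zero <- spectralStack(array(0, c(25, 10, 10)), wavelengths(lib),
                        corrected = TRUE)
  roi <- matrix(FALSE, 10, 10)
  roi[1:5, 1:10] <- TRUE                    # 50-pixel ROI
  cfg <- tsaConfig(roi, "Cal520", "LU", aGrid = seq(0, 30, 1),
                   tppcThreshold = 15)
  tp <- runTPPC(zero, cfg, lib)
  expect_true(all(tp$count[tp$a < 15] == 0))
  expect_true(all(tp$count[tp$a > 15] == sum(roi)))
  expect_equal(tp$count[tp$a == 0], 0)      # no false positives at a = 0
})

test_that("positive-pixel counts equal brute-force enumeration on noisy
           input", {
  lib <- injLib()
  set.seed(6)
  st <- stackFromPixels(
    pmax(matrix(rnorm(25 * 64, 15, 5), 25, 64), 0), c(8L, 8L),
    wavelengths(lib))
  roi <- matrix(FALSE, 8, 8); roi[2:5, 2:6] <- TRUE
  for (det in c("LU", "SAM")) {
    cfg <- tsaConfig(roi, "Cal520", det, aGrid = c(0, 2, 4))
    tp <- runTPPC(st, cfg, lib)
    for (k in seq_along(cfg@aGrid)) {
      m <- applyDetector(injectTarget(st, roi, "Cal520", cfg@aGrid[k],
                                      lib), lib, "Cal520", det)
      v <- as.vector(mapValues(m))
      expected <- if (det == "SAM") sum(v < cfg@tppcThreshold)
                  else sum(v > cfg@tppcThreshold)
      expect_equal(tp$count[k], expected)
    }
  }
})

test_that("ROC reaches AUC 1 for perfectly separated outputs and matches
           brute-force confusion counting", {
  roi <- matrix(FALSE, 8, 8); roi[3:6, 3:6] <- TRUE
  set.seed(8)
  v <- matrix(runif(64, 0, 10), 8, 8)
  v[roi] <- v[roi] + 20                     # all ROI values above the rest
  m <- new("DetectionMap", values = v, endmember = "t",
           kind = "abundance", algorithm = "MF",
           positiveDirection = "greater")
  grid <- seq(0, 35, length.out = 10)
  out <- rocFromMap(m, roi, grid)
  expect_equal(out$auc, 1.0)

  # brute-force confusion-matrix oracle at every threshold
  for (k in seq_along(grid)) {
    tp <- fp <- 0
    for (i in 1:8) for (j in 1:8) {
      if (v[i, j] > grid[k]) {
        if (roi[i, j]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    row <- out$roc[!is.na(out$roc$threshold) &
                   out$roc$threshold == grid[k], ]
    expect_equal(row$tpr, tp / sum(roi))
    expect_equal(row$fpr, fp / sum(!roi))
  }
  expect_error(rocFromMap(m, matrix(TRUE, 8, 8), grid), "neither empty")
})

test_that("ROC on ROI-independent noise sits at chance level", {
  roi <- matrix(FALSE, 12, 12); roi[3:8, 3:8] <- TRUE
  aucs <- vapply(1:24, function(s) {
    set.seed(s)
    m <- new("DetectionMap",
             values = matrix(rnorm(144), 12, 12), endmember = "t",
             kind = "abundance", algorithm = "MF",
             positiveDirection = "greater")
    rocFromMap(m, roi, seq(-3, 3, length.out = 60))$auc
  }, 0)
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-8)
})

test_that("AUC is invariant under strictly monotone transforms of the
           detector output", {
  set.seed(14)
  roi <- matrix(FALSE, 9, 9); roi[2:5, 2:7] <- TRUE
  v <- matrix(rnorm(81, 5, 2), 9, 9); v[roi] <- v[roi] + 2
  m1 <- new("DetectionMap", values = v, endmember = "t",
            kind = "abundance", algorithm = "LU",
            positiveDirection = "greater")
  grid <- sort(unique(as.vector(v)))
  out1 <- rocFromMap(m1, roi, grid)
  m2 <- new("DetectionMap", values = exp(v / 4), endmember = "t",
            kind = "abundance", algorithm = "LU",
            positiveDirection = "greater")
  out2 <- rocFromMap(m2, roi, exp(grid / 4))   # matched thresholds
  expect_equal(out2$roc$fpr, out1$roc$fpr)
  expect_equal(out2$roc$tpr, out1$roc$tpr)
  expect_equal(out2$auc, out1$auc)
})

test_that("the minimum detectable limit is the first grid value clear of
           the background outputs", {
  lib <- injLib()
  # background whose maximum LU output is known: pure Cal520 at 12.3
  r <- getSpectrum(lib, "Cal520")
  X <- matrix(r * 0.5, 25, 16)
  X[, 6] <- r * 12.3
  st <- stackFromPixels(X, c(4L, 4L), wavelengths(lib))
  roi <- matrix(FALSE, 4, 4); roi[1:2, 1:2] <- TRUE
  cfg <- tsaConfig(roi, "Cal520", "LU", thresholdGrid = 0:50)
  expect_equal(estimateMDL(st, cfg, lib), 13)

  zero <- spectralStack(array(0, c(25, 4, 4)), wavelengths(lib),
                        corrected = TRUE)
  expect_equal(estimateMDL(zero, cfg, lib), 1)  # smallest positive value

  # noisy background with tolerance: quantile oracle over the sorted
  # output distribution
  set.seed(83)
  af <- getSpectrum(lib, "AF")
  Xn <- pmax(matrix(af * 18, 25, 400) + rnorm(25 * 400, 0, 3), 0)
  stn <- stackFromPixels(Xn, c(20L, 20L), wavelengths(lib))
  tol <- 0.01
  got <- estimateMDL(stn, cfg, lib, fpTolerance = tol)
  v <- as.vector(mapValues(applyDetector(stn, lib, "Cal520", "LU")))
  oracle <- NA
  for (t in 0:50) if (sum(v >= t) / length(v) <= tol) { oracle <- t; break }
  expect_equal(got, oracle)
})

test_that("runTSA bundles consistent components and writes them to disk", {
  lib <- injLib()
  set.seed(2)
  st <- stackFromPixels(
    pmax(matrix(getSpectrum(lib, "AF") * 15, 25, 64) +
           rnorm(25 * 64, 0, 2), 0),
    c(8L, 8L), wavelengths(lib))
  roi <- matrix(FALSE, 8, 8); roi[2:5, 3:6] <- TRUE
  cfg <- tsaConfig(roi, "Cal520", "MF", aGrid = 0:6,
                   thresholdGrid = 0:30)
  res <- runTSA(st, cfg, lib)
  expect_s4_class(res, "TSAResult")
  expect_equal(nrow(res@tsc), 7L)
  expect_true(res@auc >= 0 && res@auc <= 1)
  expect_true(all(res@roc$fpr >= 0 & res@roc$fpr <= 1))
  expect_true(all(res@tppc$count >= 0 & res@tppc$count <= 64))
  d <- file.path(tempdir(), "tsaout")
  writeTSA(res, d)
  expect_true(all(file.exists(file.path(d, c("tsc.csv", "tppc.csv",
                                             "roc.csv",
                                             "summary.json")))))
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(js$auc, res@auc, tolerance = 1e-12)

  pdf(NULL)
  expect_no_error(plot(res))
  dev.off()
})
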