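abundMap <- function(v) new("DetectionMap", values = v, endmember = "Ca",
                            kind = "abundance", algorithm = "MF",
                            positiveDirection = "greater")

test_that("Otsu separates a clean bimodal image and refuses a constant
           one", {
  v <- matrix(c(rep(0, 32), rep(100, 32)), 8, 8)
  t <- otsuThreshold(v)
  expect_gt(t, 0)
  expect_lt(t, 100)
  expect_error(otsuThreshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Otsu equals exhaustive between-class-variance search", {
  # two-point distributions with unequal class weights
  for (s in 1:5) {
    set.seed(s)
    vals <- sample(0:255, 2)
    v <- c(rep(min(vals), sample(5:50, 1)),
           rep(max(vals), sample(5:50, 1)))
    expect_equal(otsuThreshold(v), otsuOracle(v))
  }
  # random 8-bit images
  for (s in 1:20) {
    set.seed(100 + s)
    v <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(otsuThreshold(v), otsuOracle(as.vector(v)))
  }
  # and real-valued detector output
  for (s in 1:5) {
    set.seed(200 + s)
    v <- c(rnorm(150, 2, 1), rnorm(100, 14, 3))
    expect_equal(otsuThreshold(v, nBins = 128L),
                 otsuOracle(v, nBins = 128L))
  }
})

test_that("applyFilter implements strict directional thresholding", {
  set.seed(41)
  v <- matrix(runif(30, 0, 10), 5, 6)
  m <- abundMap(v)
  expect_true(all(applyFilter(m, pixelFilter(0, "none"))))
  expect_false(any(applyFilter(m, pixelFilter(11, "manual"))))
  t <- 4.2
  expect_identical(applyFilter(m, pixelFilter(t, "manual")), v > t)
  ang <- new("DetectionMap", values = v / 10 * pi, endmember = "Ca",
             kind = "angle", algorithm = "SAM",
             positiveDirection = "less")
  expect_identical(applyFilter(ang, pixelFilter(1, "manual", "less")),
                   v / 10 * pi < 1)
})

test_that("constant maps yield a constant trace; empty-pass frames yield
           NA", {
  maps <- lapply(1:4, function(i) abundMap(matrix(7, 4, 4)))
  tr <- extractTrace(maps, matrix(TRUE, 4, 4), pixelFilter(0, "none"))
  expect_equal(tr@values, rep(7, 4))
  expect_equal(tr@nPixels, rep(16L, 4))

  maps[[3]] <- abundMap(matrix(0, 4, 4))
  trf <- extractTrace(maps, matrix(TRUE, 4, 4),
                      pixelFilter(5, "manual"))
  expect_equal(trf@nPixels[3], 0L)
  expect_true(is.na(trf@values[3]))
  expect_false(any(is.na(trf@values[-3])))
})

test_that("pixel filtering amplifies the oscillation of a partially
           responding cell (closed-form mixture of means)", {
  # 20% of pixels oscillate with amplitude A above threshold; 80% sit at a
  # constant low value below it. Unfiltered amplitude is 0.2*A, filtered
  # amplitude is A.
  A <- 10
  nF <- 20L
  osc <- A / 2 * (1 + sin(2 * pi * seq_len(nF) / 4)) + 20
  maps <- lapply(seq_len(nF), function(f) {
    v <- matrix(1, 10, 10)                  # 80 low pixels at 1
    v[1:2, ] <- osc[f]                      # 20 oscillating pixels
    abundMap(v)
  })
  region <- matrix(TRUE, 10, 10)
  unf <- extractTrace(maps, region, pixelFilter(0, "none"))
  fil <- extractTrace(maps, region, pixelFilter(15, "tsa"))
  ampU <- diff(range(unf@values))
  ampF <- diff(range(fil@values))
  expect_equal(ampU, 0.2 * A, tolerance = 1e-9)
  expect_equal(ampF, A, tolerance = 1e-9)
  expect_gte(ampF, 3 * ampU)
})

test_that("the whole-field trace steps up at the programmed agonist
           onset", {
  r <- renderScene(exampleScene("calcium", noise = "none"))
  lib <- r$truth@library
  op <- mfBuild(lib, "Cal520")
  maps <- lapply(r$stacks, function(s) mfApply(op, s))
  times <- vapply(r$stacks, function(s) s@timeS, 0)
  tr <- extractTrace(maps, matrix(TRUE, 96, 96), pixelFilter(0, "none"),
                     timesS = times)
  pre <- tr@values[times < 300]
  expect_lt(diff(range(pre)), 1e-9)         # flat baseline
  onset <- tr@values[times == 300] - tr@values[times == 270]
  expect_gt(onset, 5 * max(abs(diff(pre)), 1e-12))
  expect_gt(onset, 0.1 * mean(pre))
  # ground-truth comparison: the MF trace mirrors the true mean abundance
  truth <- apply(r$truth@abundances[["Cal520"]], 3, mean)
  gain <- sum(op@filterVector * getSpectrum(lib, "Cal520"))
  leak <- tr@values - gain * truth
  expect_lt(diff(range(leak)) / mean(tr@values), 1e-9)
})

test_that("filtering never changes the trace of a fully passing region and
           never lowers an abundance trace", {
  set.seed(17)
  maps <- lapply(1:6, function(f)
    abundMap(matrix(runif(64, 5, 30), 8, 8)))
  region <- matrix(FALSE, 8, 8); region[2:6, 2:6] <- TRUE
  unf <- extractTrace(maps, region, pixelFilter(0, "none"))
  # every pixel exceeds threshold 4: the well-labeled-cell case
  fil4 <- extractTrace(maps, region, pixelFilter(4, "tsa"))
  expect_equal(fil4@values, unf@values)
  expect_equal(fil4@nPixels, unf@nPixels)
  # a binding threshold can only raise the mean of the surviving pixels
  for (t in c(10, 18, 25)) {
    filt <- extractTrace(maps, region, pixelFilter(t, "manual"))
    expect_true(all(filt@values >= unf@values, na.rm = TRUE))
  }
})

test_that("reference-frame filtering freezes the pass mask", {
  v1 <- matrix(c(10, 0, 0, 10), 2, 2)
  v2 <- matrix(c(0, 10, 10, 0), 2, 2)
  maps <- list(abundMap(v1), abundMap(v2))
  region <- matrix(TRUE, 2, 2)
  per <- extractTrace(maps, region, pixelFilter(5, "manual"),
                      filterMode = "per_frame")
  ref <- extractTrace(maps, region, pixelFilter(5, "manual"),
                      filterMode = "reference_frame", referenceFrame = 1L)
  expect_equal(per@values, c(10, 10))
  expect_equal(ref@values, c(10, 0))        # frame-1 mask applied to frame 2
})

test_that("trace CSV round-trips through writeTrace", {
  maps <- lapply(1:3, function(f) abundMap(matrix(f * 1.5, 3, 3)))
  tr <- extractTrace(maps, matrix(TRUE, 3, 3), pixelFilter(0, "none"),
                     timesS = c(0, 30, 60), maskName = "field")
  path <- file.path(tempdir(), "trace.csv")
  writeTrace(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$time_s, c(0, 30, 60))
  expect_equal(back$mean, c(1.5, 3, 4.5))
  expect_equal(back$n_pixels, rep(9L, 3))
})
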