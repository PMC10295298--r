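#' Configure a theoretical sensitivity analysis
#'
#' Supplies defaults mirroring a Ca2+-label detection study on
#' excitation-scanning data: injection scalars in increments of 1 (0-30 for
#' LU and MF, 0-25 for SAM and CEM), ROC injection level 5, positive-pixel
#' threshold 15 (0.98 radians for SAM), and ROC thresholds 0-50 in steps of
#' 1 (0-1.8 radians in 51 steps for SAM).
#'
#' @param roi logical matrix: the injection region.
#' @param target target endmember name.
#' @param detector one of \code{"LU"}, \code{"SAM"}, \code{"CEM"},
#'   \code{"MF"}.
#' @param aGrid ascending injection scalars containing 0.
#' @param rocScale injection level for the ROC threshold sweep.
#' @param tppcThreshold detection threshold for the positive-pixel curve.
#' @param thresholdGrid ascending thresholds for the ROC sweep.
#' @return a \linkS4class{TSAConfig}.
#' @export
tsaConfig <- function(roi, target, detector = c("LU", "SAM", "CEM", "MF"),
                      aGrid = NULL, rocScale = 5, tppcThreshold = NULL,
                      thresholdGrid = NULL) {
  detector <- match.arg(detector)
  sam <- detector == "SAM"
  if (is.null(aGrid))
    aGrid <- if (detector %in% c("LU", "MF")) 0:30 else 0:25
  if (is.null(tppcThreshold)) tppcThreshold <- if (sam) 0.98 else 15
  if (is.null(thresholdGrid))
    thresholdGrid <- if (sam) seq(0, 1.8, length.out = 51L) else 0:50
  new("TSAConfig", roi = roi, target = target,
      aGrid = as.numeric(aGrid), rocScale = as.numeric(rocScale),
      tppcThreshold = as.numeric(tppcThreshold),
      thresholdGrid = as.numeric(thresholdGrid), detector = detector)
}

#' Inject scaled target endmember signal into an ROI
#'
#' Adds \code{a} times the target spectrum to every pixel inside the ROI,
#' x' = x + a r, leaving pixels outside untouched. This creates a region
#' with a known simulated ground truth for the target signature inside an
#' otherwise real (or synthetic) background image.
#'
#' @param stack a corrected \linkS4class{SpectralStack}.
#' @param roi logical matrix.
#' @param target numeric target spectrum, or an endmember name looked up in
#'   \code{library}.
#' @param a nonnegative injection scalar.
#' @param library optional \linkS4class{SpectralLibrary} for name lookup.
#' @return the injected \linkS4class{SpectralStack}.
#' @export
injectTarget <- function(stack, roi, target, a, library = NULL) {
  stopIfNot(a >= 0, "injectTarget: a must be >= 0")
  stopIfNot(all(dim(roi) == dim(stack@data)[2:3]),
            "injectTarget: ROI shape does not match stack")
  tg <- resolveTarget(target, library, nBands(stack))
  if (a == 0 || !any(roi)) return(stack)
  d <- stack@data
  X <- pixelMatrix(d)
  idx <- which(as.vector(roi))
  X[, idx] <- X[, idx] + a * tg$spectrum
  spectralStack(array(X, dim(d)), stack@wavelengths, timeS = stack@timeS,
                saturationValue = stack@saturationValue,
                corrected = stack@corrected)
}

# Positive-detection mask of a map at a threshold, honoring the map's
# positive direction (strictly above for abundance, strictly below for
# angle).
positiveMask <- function(map, threshold) {
  if (map@positiveDirection == "greater") map@values > threshold
  else map@values < threshold
}

detectorForConfig <- function(stack, config, library)
  applyDetector(stack, library, config@target, config@detector)

#' Theoretical sensitivity curve
#'
#' For each injection level a, injects a times the target spectrum into the
#' ROI, runs the configured detector, and summarizes the detector output
#' over the ROI pixels (mean, standard deviation and the full
#' distribution). An ordinary least-squares line is fitted to the
#' (a, mean) pairs; its slope, intercept and R-squared describe the
#' linearity of the detector's response.
#'
#' @param stack background \linkS4class{SpectralStack} (no target present).
#' @param config a \linkS4class{TSAConfig}.
#' @param library a \linkS4class{SpectralLibrary}.
#' @return list with \code{tsc} (data.frame a/mean/sd), \code{values}
#'   (list of ROI output vectors) and \code{fit} (slope, intercept, r2).
#' @export
runTSC <- function(stack, config, library) {
  roiIdx <- which(as.vector(config@roi))
  stopIfNot(length(roiIdx) > 0, "runTSC: empty ROI")
  vals <- lapply(config@aGrid, function(a) {
    m <- detectorForConfig(injectTarget(stack, config@roi, config@target,
                                        a, library),
                           config, library)
    as.vector(m@values)[roiIdx]
  })
  mu <- vapply(vals, mean, 0)
  sdv <- vapply(vals, stats::sd, 0)
  fit <- stats::lm(mu ~ config@aGrid)
  ss <- sum((mu - mean(mu))^2)
  r2 <- if (ss > 0) 1 - sum(stats::residuals(fit)^2) / ss else 1
  list(tsc = data.frame(a = config@aGrid, mean = mu, sd = sdv),
       values = vals,
       fit = c(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]), r2 = r2))
}

#' Thresholded positive pixel curve
#'
#' For each injection level, counts the pixels of the whole image whose
#' detector output is a positive detection at the configured threshold
#' (above it for abundance maps, below it for angle maps). The count at
#' a = 0 is the baseline false-positive level; the steepness of the rise
#' past the threshold reflects the detector's discrimination ability.
#'
#' @inheritParams runTSC
#' @return data.frame with columns \code{a}, \code{count}.
#' @export
runTPPC <- function(stack, config, library) {
  counts <- vapply(config@aGrid, function(a) {
    m <- detectorForConfig(injectTarget(stack, config@roi, config@target,
                                        a, library),
                           config, library)
    sum(positiveMask(m, config@tppcThreshold))
  }, 0L)
  data.frame(a = config@aGrid, count = counts)
}

#' ROC curve and AUC from a detection map
#'
#' Sweeps the threshold grid over a detection map given the ground-truth
#' positive region: TPR = true positives / ROI size, FPR = false positives
#' / pixels outside the ROI. Points are sorted by FPR and the (0,0) and
#' (1,1) endpoints appended; the AUC is computed by the trapezoid rule.
#'
#' @param map a \linkS4class{DetectionMap}.
#' @param roi logical matrix of true-positive pixels (neither empty nor the
#'   whole image).
#' @param thresholdGrid ascending thresholds.
#' @return list with \code{roc} (data.frame threshold/fpr/tpr) and
#'   \code{auc}.
#' @export
rocFromMap <- function(map, roi, thresholdGrid) {
  nPos <- sum(roi)
  nNeg <- sum(!roi)
  stopIfNot(nPos > 0 && nNeg > 0,
            "rocFromMap: ROI must be neither empty nor the whole image")
  pts <- vapply(thresholdGrid, function(t) {
    pos <- positiveMask(map, t)
    c(fpr = sum(pos & !roi) / nNeg, tpr = sum(pos & roi) / nPos)
  }, c(fpr = 0, tpr = 0))
  roc <- data.frame(threshold = thresholdGrid, fpr = pts["fpr", ],
                    tpr = pts["tpr", ])
  roc <- rbind(data.frame(threshold = NA_real_, fpr = 0, tpr = 0),
               roc,
               data.frame(threshold = NA_real_, fpr = 1, tpr = 1))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' ROC curve for a configured sensitivity analysis
#'
#' Injects the target at the fixed level \code{rocScale}, runs the
#' detector, and computes the ROC over the configured threshold grid with
#' the ROI as ground truth.
#'
#' @inheritParams runTSC
#' @return list with \code{roc} and \code{auc} (see
#'   \code{\link{rocFromMap}}).
#' @export
runROC <- function(stack, config, library) {
  m <- detectorForConfig(
    injectTarget(stack, config@roi, config@target, config@rocScale,
                 library),
    config, library)
  rocFromMap(m, config@roi, config@thresholdGrid)
}

#' Estimate the minimum detectable limit
#'
#' Scans the threshold grid at zero injected signal and returns the
#' smallest threshold (largest for angle maps, whose positive direction is
#' inverted) at which the whole-image false-positive fraction does not
#' exceed \code{fpTolerance}. A pixel counts as a false positive here when
#' its output reaches the threshold (>= for abundance maps, <= for angle
#' maps), so with the default tolerance 0 the MDL is the first grid value
#' strictly beyond the background output range. Returns \code{NA} with a
#' warning if no grid threshold qualifies.
#'
#' @inheritParams runTSC
#' @param fpTolerance acceptable false-positive fraction in [0, 1).
#' @return numeric(1): the minimum detectable limit in detector-output
#'   units.
#' @export
estimateMDL <- function(stack, config, library, fpTolerance = 0) {
  stopIfNot(fpTolerance >= 0 && fpTolerance < 1,
            "estimateMDL: fpTolerance must be in [0, 1)")
  m <- detectorForConfig(stack, config, library)
  v <- as.vector(m@values)
  n <- length(v)
  grid <- config@thresholdGrid
  if (m@positiveDirection == "greater") {
    frac <- vapply(grid, function(t) sum(v >= t) / n, 0)
    ok <- which(frac <= fpTolerance)
    if (!length(ok)) { warning("no grid threshold meets the tolerance");
                       return(NA_real_) }
    grid[min(ok)]
  } else {
    frac <- vapply(grid, function(t) sum(v <= t) / n, 0)
    ok <- which(frac <= fpTolerance)
    if (!length(ok)) { warning("no grid threshold meets the tolerance");
                       return(NA_real_) }
    grid[max(ok)]
  }
}

#' Run the full theoretical sensitivity analysis
#'
#' Convenience wrapper producing the sensitivity curve, positive-pixel
#' curve, ROC curve with AUC, and the minimum detectable limit in one
#' \linkS4class{TSAResult}.
#'
#' @inheritParams estimateMDL
#' @return a \linkS4class{TSAResult}.
#' @examples
#' \donttest{
#' r <- renderScene(exampleScene("background", seed = 7))
#' roi <- exampleROI(r$truth)
#' cfg <- tsaConfig(roi, "Cal520", "MF")
#' runTSA(r$stacks[[1]], cfg, r$truth@library)
#' }
#' @export
runTSA <- function(stack, config, library, fpTolerance = 0) {
  tsc <- runTSC(stack, config, library)
  tppc <- runTPPC(stack, config, library)
  roc <- runROC(stack, config, library)
  mdl <- estimateMDL(stack, config, library, fpTolerance)
  new("TSAResult", tsc = tsc$tsc, tscValues = tsc$values, fit = tsc$fit,
      tppc = tppc, roc = roc$roc, auc = roc$auc, mdl = mdl,
      detector = config@detector, target = config@target)
}

#' Plot a theoretical sensitivity analysis result
#'
#' Draws the three diagnostic curves side by side: the sensitivity curve
#' with error bars and its linear fit, the positive-pixel curve with the
#' configured threshold behavior, and the ROC curve annotated with the
#' AUC.
#'
#' @param x a \linkS4class{TSAResult}.
#' @param y ignored.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
setMethod("plot", signature(x = "TSAResult", y = "missing"),
  function(x, y, ...) {
    op <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(op))
    with(x@tsc, {
      plot(a, mean, pch = 15, xlab = "added endmember signal (a)",
           ylab = "detector output", main = paste0("TSC (", x@detector,
                                                   ")"), ...)
      graphics::arrows(a, mean - sd, a, mean + sd, angle = 90, code = 3,
                       length = 0.02, col = "red")
      graphics::abline(x@fit[["intercept"]], x@fit[["slope"]])
    })
    plot(x@tppc$a, x@tppc$count, type = "b", pch = 16,
         xlab = "added endmember signal (a)", ylab = "positive pixels",
         main = "TPPC")
    plot(x@roc$fpr, x@roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "false-positive rate", ylab = "true-positive rate",
         main = sprintf("ROC (AUC = %.3f)", x@auc))
    graphics::abline(0, 1, lty = 3)
    invisible(x)
  })

#' Write sensitivity-analysis curves to CSV plus a JSON summary
#'
#' Writes \code{tsc.csv}, \code{tppc.csv} and \code{roc.csv} under
#' \code{dir}, plus \code{summary.json} holding the AUC, MDL and linear
#' fit.
#'
#' @param result a \linkS4class{TSAResult}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeTSA <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result@tsc, file.path(dir, "tsc.csv"),
                   row.names = FALSE)
  utils::write.csv(result@tppc, file.path(dir, "tppc.csv"),
                   row.names = FALSE)
  utils::write.csv(result@roc, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(detector = result@detector, target = result@target,
         auc = result@auc, mdl = result@mdl,
         slope = result@fit[["slope"]],
         intercept = result@fit[["intercept"]], r2 = result@fit[["r2"]]),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
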