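detectionMap <- function(values, endmember, kind, algorithm) {
  new("DetectionMap", values = values, endmember = endmember, kind = kind,
      algorithm = algorithm,
      positiveDirection = if (kind == "angle") "less" else "greater")
}

# Resolve a target given either a bare spectrum or an endmember name plus
# library; returns list(spectrum, name).
resolveTarget <- function(target, library = NULL, nb = NULL) {
  if (is.character(target)) {
    stopIfNot(!is.null(library),
              "a library is required to resolve target '", target, "'")
    list(spectrum = getSpectrum(library, target), name = target)
  } else {
    sp <- as.numeric(target)
    if (!is.null(nb))
      stopIfNot(length(sp) == nb, "target spectrum band count mismatch")
    list(spectrum = sp, name = "target")
  }
}

#' Non-negatively constrained linear unmixing
#'
#' Estimates, for every pixel, the nonnegative endmember abundances a that
#' minimize the least-squares residual of the linear mixing model
#' x = sum(a_i r_i) + w, where x is the pixel spectrum and r_i the
#' peak-normalized library spectra. Solved with a Lawson-Hanson active-set
#' method batched across pixels. The per-pixel root-mean-square of the
#' residual over bands is returned alongside the abundance maps.
#'
#' @param stack a corrected \linkS4class{SpectralStack}.
#' @param library a \linkS4class{SpectralLibrary} on the same band grid.
#' @return an \linkS4class{UnmixResult}.
#' @examples
#' wl <- seq(360, 480, by = 5)
#' lib <- makeLibrary(exampleModels(), wl)
#' px <- 2 * getSpectrum(lib, "Cal520") + 3 * getSpectrum(lib, "AF")
#' st <- spectralStack(array(px, c(25, 1, 1)), wl, corrected = TRUE)
#' round(sapply(unmixLU(st, lib)@maps, mapValues), 6)
#' @export
unmixLU <- function(stack, library) {
  stopIfNot(nBands(stack) == nBands(library),
            "unmixLU: stack and library band counts differ")
  shape <- dim(stack@data)[2:3]
  X <- pixelMatrix(stack@data)
  A <- t(library@spectra)
  coef <- nnlsBatch(A, X)
  resid <- X - A %*% coef
  rms <- asImage(sqrt(colMeans(resid^2)), shape)
  maps <- setNames(lapply(seq_along(library@names), function(i)
    detectionMap(asImage(coef[i, ], shape), library@names[i],
                 "abundance", "LU")), library@names)
  new("UnmixResult", maps = maps, rmsError = rms)
}

#' Spectral angle mapper
#'
#' Computes, per pixel, the angle between the pixel spectrum and the target
#' spectrum: theta = arccos((r . x) / (||r|| ||x||)), in radians. The angle
#' is invariant to positive scaling of either spectrum, so SAM classifies
#' by spectral shape only. Pixels with zero norm are assigned pi/2
#' (maximally non-target) so that thresholding remains total. Small angles
#' indicate similarity, hence the map's positive direction is "less".
#'
#' @param stack a corrected \linkS4class{SpectralStack}.
#' @param target numeric target spectrum, or an endmember name looked up in
#'   \code{library}.
#' @param library optional \linkS4class{SpectralLibrary} for name lookup.
#' @return a \linkS4class{DetectionMap} of kind \code{"angle"}.
#' @export
samAngle <- function(stack, target, library = NULL) {
  tg <- resolveTarget(target, library, nBands(stack))
  r <- tg$spectrum
  rn <- sqrt(sum(r^2))
  stopIfNot(rn > 0, "samAngle: zero target spectrum")
  X <- pixelMatrix(stack@data)
  xn <- sqrt(colSums(X^2))
  cosv <- as.vector(crossprod(r, X)) / (rn * pmax(xn, .Machine$double.xmin))
  theta <- acos(pmin(pmax(cosv, -1), 1))
  theta[xn == 0] <- pi / 2
  detectionMap(asImage(theta, dim(stack@data)[2:3]), tg$name, "angle", "SAM")
}

#' Build a constrained energy minimization filter
#'
#' Forms the sample correlation matrix R of all image pixel spectra,
#' R = sum_j x_j x_j' / (k l), and the CEM operator
#' L = R^-1 r / (r' R^-1 r), which has unity gain on the target spectrum r
#' while minimizing the average output energy over the image. When R is
#' ill-conditioned a ridge term \code{ridge * trace(R)/B} is added to its
#' diagonal before inversion.
#'
#' @param stack a corrected \linkS4class{SpectralStack} (supplies R).
#' @param target numeric target spectrum, or an endmember name looked up in
#'   \code{library}.
#' @param library optional \linkS4class{SpectralLibrary} for name lookup.
#' @param ridge relative ridge weight used when R is numerically singular.
#' @return a \linkS4class{CEMFilter}.
#' @seealso \code{\link{cemApply}}
#' @export
cemBuild <- function(stack, target, library = NULL, ridge = 1e-9) {
  tg <- resolveTarget(target, library, nBands(stack))
  X <- pixelMatrix(stack@data)
  R <- tcrossprod(X) / ncol(X)
  solveR <- function(M) tryCatch({
    if (rcond(M) < 1e-12) stop("ill-conditioned")
    solve(M, tg$spectrum)
  }, error = function(e) NULL)
  v <- solveR(R)
  if (is.null(v)) {
    Rr <- R + diag(ridge * sum(diag(R)) / nrow(R), nrow(R))
    v <- solveR(Rr)
    if (is.null(v))
      stop("cemBuild: correlation matrix singular even after ridge ",
           "regularization (numerical conditioning)")
  }
  L <- v / sum(tg$spectrum * v)
  new("CEMFilter", operator = as.numeric(L), correlation = R,
      target = tg$name, targetSpectrum = tg$spectrum)
}

#' Apply a CEM filter to a stack
#'
#' @param filter a \linkS4class{CEMFilter}.
#' @param stack a \linkS4class{SpectralStack} with matching band count.
#' @return a \linkS4class{DetectionMap} (abundance-like, unity gain on the
#'   target spectrum).
#' @export
cemApply <- function(filter, stack) {
  stopIfNot(length(filter@operator) == nBands(stack),
            "cemApply: band count mismatch")
  X <- pixelMatrix(stack@data)
  v <- as.vector(crossprod(filter@operator, X))
  detectionMap(asImage(v, dim(stack@data)[2:3]), filter@target,
               "abundance", "CEM")
}

#' Build a matched-filter rejection operator
#'
#' Collects the non-target library spectra as columns of U, forms the
#' pseudo-inverse U# = (U'U)^-1 U' and the rejection operator
#' P = I - U U#, an orthogonal projector onto the complement of the
#' background subspace (P is symmetric, idempotent, and annihilates every
#' background spectrum). The filter vector is q = r' P for the target
#' spectrum r; applying the filter gives a = q . x per pixel. With
#' \code{normalized = TRUE} the output is additionally divided by q . r so
#' that a pure target pixel of unit abundance maps to 1.
#'
#' @param library a \linkS4class{SpectralLibrary} with >= 2 endmembers.
#' @param target target endmember name (must be in the library).
#' @param normalized divide the output by \code{q . r}? Default off.
#' @return an \linkS4class{MFOperator}.
#' @seealso \code{\link{mfApply}}
#' @export
mfBuild <- function(library, target, normalized = FALSE) {
  stopIfNot(is.character(target) && target %in% library@names,
            "mfBuild: target must name a library endmember")
  r <- getSpectrum(library, target)
  U <- t(library@spectra[library@names != target, , drop = FALSE])
  B <- nBands(library)
  if (ncol(U) > 0) {
    G <- crossprod(U)
    if (rcond(G) < 1e-12)
      stop("mfBuild: non-target spectra are linearly dependent ",
           "(numerical conditioning)")
    Usharp <- solve(G, t(U))
    P <- diag(B) - U %*% Usharp
  } else {
    Usharp <- matrix(0, 0, B)
    P <- diag(B)
  }
  new("MFOperator", rejection = P, pseudoInverse = Usharp,
      filterVector = as.numeric(r %*% P), background = U,
      target = target, targetSpectrum = r, normalized = normalized)
}

#' Apply a matched filter to a stack
#'
#' @param op an \linkS4class{MFOperator}.
#' @param stack a \linkS4class{SpectralStack} with matching band count.
#' @return a \linkS4class{DetectionMap} (abundance-like).
#' @export
mfApply <- function(op, stack) {
  stopIfNot(length(op@filterVector) == nBands(stack),
            "mfApply: band count mismatch")
  X <- pixelMatrix(stack@data)
  v <- as.vector(crossprod(op@filterVector, X))
  if (op@normalized) v <- v / sum(op@filterVector * op@targetSpectrum)
  detectionMap(asImage(v, dim(stack@data)[2:3]), op@target,
               "abundance", "MF")
}

#' Run any of the four detectors for one target endmember
#'
#' Dispatch wrapper: \code{"LU"} runs full unmixing and returns the target's
#' abundance map; \code{"SAM"}, \code{"CEM"} and \code{"MF"} run the
#' respective single-target detector.
#'
#' @param stack a corrected \linkS4class{SpectralStack}.
#' @param library a \linkS4class{SpectralLibrary}.
#' @param target target endmember name.
#' @param detector one of \code{"LU"}, \code{"SAM"}, \code{"CEM"},
#'   \code{"MF"}.
#' @param ... passed to the underlying builder (\code{ridge},
#'   \code{normalized}).
#' @return a \linkS4class{DetectionMap}.
#' @export
applyDetector <- function(stack, library, target,
                          detector = c("LU", "SAM", "CEM", "MF"), ...) {
  detector <- match.arg(detector)
  switch(detector,
    LU = unmixLU(stack, library)@maps[[target]],
    SAM = samAngle(stack, target, library),
    CEM = cemApply(cemBuild(stack, target, library, ...), stack),
    MF = mfApply(mfBuild(library, target, ...), stack))
}

#' Write detection maps as float32 TIFFs with a JSON sidecar
#'
#' One float32 TIFF per map (peak-scaled, scale recorded in the sidecar)
#' plus \code{<stem>.json} recording endmember, algorithm, kind and scale.
#'
#' @param map a \linkS4class{DetectionMap}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeDetectionMap <- function(map, path) {
  v <- map@values
  lo <- min(v)
  rng <- max(v) - lo
  if (rng == 0) rng <- 1
  tiff::writeTIFF((v - lo) / rng, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(endmember = map@endmember, algorithm = map@algorithm,
         kind = map@kind, positive_direction = map@positiveDirection,
         offset = lo, scale = rng),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetectionMap
#' @export
readDetectionMap <- function(path) {
  meta <- jsonlite::read_json(
    paste0(tools::file_path_sans_ext(path), ".json"))
  v <- tiff::readTIFF(path) * meta$scale + meta$offset
  detectionMap(v, meta$endmember, meta$kind, meta$algorithm)
}
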