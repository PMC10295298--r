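#' Extract a reference (pure endmember) spectrum from a single-label stack
#'
#' Computes the pixel-averaged spectrum over an ROI of a corrected
#' single-label control image and peak-normalizes it to a maximum of unity.
#' Pixels reaching the detector's saturation value in any band are excluded
#' before averaging — the programmatic counterpart of selecting intense but
#' not oversaturated regions by hand.
#'
#' @param stack a corrected \linkS4class{SpectralStack}.
#' @param roi logical matrix, nonempty.
#' @return numeric spectrum (length \code{nBands(stack)}), max exactly 1.
#' @seealso \code{\link{assembleLibrary}}
#' @export
extractReference <- function(stack, roi) {
  stopIfNot(is.matrix(roi) && any(roi), "extractReference: empty ROI")
  stopIfNot(all(dim(roi) == dim(stack@data)[2:3]),
            "extractReference: ROI shape does not match stack")
  X <- pixelMatrix(stack@data)[, as.vector(roi), drop = FALSE]
  if (!is.na(stack@saturationValue)) {
    sat <- apply(X >= stack@saturationValue, 2L, any)
    if (all(sat))
      stop("extractReference: every ROI pixel is saturated")
    X <- X[, !sat, drop = FALSE]
  }
  ref <- rowMeans(X)
  if (max(ref) <= 0)
    stop("extractReference: degenerate all-zero spectrum in ROI")
  peakNormalize(ref)
}

#' Assemble a spectral library from named spectra
#'
#' @param spectra named list of numeric spectra with equal band counts, or
#'   a numeric matrix (endmembers x bands) with rownames.
#' @param wavelengths ascending band centers (nm).
#' @return a \linkS4class{SpectralLibrary}; spectra are peak-normalized.
#' @examples
#' assembleLibrary(list(a = c(1, 2), b = c(2, 1)), c(400, 440))
#' @export
assembleLibrary <- function(spectra, wavelengths) {
  if (is.matrix(spectra)) {
    nms <- rownames(spectra)
    spectra <- lapply(seq_len(nrow(spectra)), function(i) spectra[i, ])
    names(spectra) <- nms
  }
  stopIfNot(length(spectra) >= 1L, "assembleLibrary: no spectra given")
  nms <- names(spectra)
  stopIfNot(!is.null(nms) && all(nzchar(nms)),
            "assembleLibrary: every spectrum must be named")
  stopIfNot(!anyDuplicated(nms), "assembleLibrary: duplicate names")
  nb <- unique(lengths(spectra))
  stopIfNot(length(nb) == 1L, "assembleLibrary: band-count mismatch")
  stopIfNot(nb == length(wavelengths),
            "assembleLibrary: wavelengths do not match band count")
  mat <- t(vapply(spectra, function(s) peakNormalize(as.numeric(s)),
                  numeric(nb)))
  new("SpectralLibrary", names = nms, spectra = mat,
      wavelengths = as.numeric(wavelengths))
}

#' Write / read a spectral library CSV
#'
#' The CSV layout is one row per band with header
#' \code{wavelength_nm,<name1>,<name2>,...}; values round-trip to at least
#' 12 significant digits.
#'
#' @param library a \linkS4class{SpectralLibrary}.
#' @param path CSV path.
#' @return \code{writeLibrary}: \code{path} invisibly; \code{readLibrary}:
#'   a \linkS4class{SpectralLibrary}.
#' @export
writeLibrary <- function(library, path) {
  tab <- data.frame(wavelength_nm = library@wavelengths,
                    t(library@spectra), check.names = FALSE)
  names(tab) <- c("wavelength_nm", library@names)
  utils::write.csv(format(tab, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  stopIfNot(names(tab)[1L] == "wavelength_nm",
            "library CSV must start with a wavelength_nm column: ", path)
  stopIfNot(ncol(tab) >= 2L, "library CSV has no endmember columns: ", path)
  new("SpectralLibrary", names = names(tab)[-1L],
      spectra = t(as.matrix(tab[, -1L, drop = FALSE])),
      wavelengths = tab$wavelength_nm)
}
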