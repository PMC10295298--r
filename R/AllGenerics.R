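#' Accessors for hsiDetect objects
#'
#' Small accessor generics used across the package: \code{wavelengths} for
#' the wavelength axis, \code{stackData} for the raw (band, row, col) array,
#' \code{mapValues} for a detection map's image, \code{endmemberNames} for
#' library/endmember labels, and \code{nBands} for the band count.
#'
#' @param object an hsiDetect S4 object.
#' @return The slot content named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("endmemberNames",
           function(object) standardGeneric("endmemberNames"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("isCorrected", function(object) standardGeneric("isCorrected"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralStack", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralLibrary",
          function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "CorrectionProfile",
          function(object) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("stackData", "SpectralStack", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("mapValues", "DetectionMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("endmemberNames", "SpectralLibrary", function(object) object@names)

#' @rdname accessors
#' @export
setMethod("nBands", "SpectralStack", function(object) dim(object@data)[1L])

#' @rdname accessors
#' @export
setMethod("nBands", "SpectralLibrary",
          function(object) ncol(object@spectra))

#' @rdname accessors
#' @export
setMethod("isCorrected", "SpectralStack", function(object) object@corrected)

#' Library spectra matrix
#'
#' @param object a \linkS4class{SpectralLibrary}.
#' @return numeric matrix (endmembers x bands), rows named by endmember.
#' @export
setGeneric("spectraMatrix", function(object) standardGeneric("spectraMatrix"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectralLibrary", function(object) {
  m <- object@spectra
  dimnames(m) <- list(object@names, NULL)
  m
})

#' Extract one endmember spectrum from a library
#'
#' @param object a \linkS4class{SpectralLibrary}.
#' @param name endmember name.
#' @return numeric vector of length \code{nBands(object)}.
#' @export
setGeneric("getSpectrum",
           function(object, name) standardGeneric("getSpectrum"))

#' @rdname getSpectrum
#' @export
setMethod("getSpectrum", "SpectralLibrary", function(object, name) {
  i <- match(name, object@names)
  if (is.na(i))
    stop("unknown endmember '", name, "' (library has: ",
         paste(object@names, collapse = ", "), ")")
  object@spectra[i, ]
})

## ---- show methods ------------------------------------------------------

setMethod("show", "SpectralStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SpectralStack: %d bands x %d x %d pixels, %g-%g nm%s%s\n",
    d[1L], d[2L], d[3L], min(object@wavelengths), max(object@wavelengths),
    if (!is.na(object@timeS)) sprintf(", t = %gs", object@timeS) else "",
    if (object@corrected) " (corrected)" else " (raw)"))
})

setMethod("show", "SpectralLibrary", function(object) {
  cat(sprintf("SpectralLibrary: %d endmembers x %d bands (%g-%g nm)\n",
              nrow(object@spectra), ncol(object@spectra),
              min(object@wavelengths), max(object@wavelengths)))
  cat("  endmembers:", paste(object@names, collapse = ", "), "\n")
})

setMethod("show", "DetectionMap", function(object) {
  cat(sprintf("DetectionMap [%s] for '%s': %d x %d %s image (positive = %s)\n",
              object@algorithm, object@endmember,
              nrow(object@values), ncol(object@values),
              object@kind, object@positiveDirection))
})

setMethod("show", "UnmixResult", function(object) {
  cat(sprintf("UnmixResult: %d endmember abundance maps, RMS error %d x %d\n",
              length(object@maps), nrow(object@rmsError),
              ncol(object@rmsError)))
  cat("  endmembers:", paste(names(object@maps), collapse = ", "), "\n")
})

setMethod("show", "TSAResult", function(object) {
  cat(sprintf("TSAResult [%s] target '%s'\n", object@detector,
              object@target))
  cat(sprintf("  TSC: %d injection levels, slope %.4g, R^2 %.4g\n",
              nrow(object@tsc), object@fit[["slope"]], object@fit[["r2"]]))
  cat(sprintf("  ROC: AUC %.4g; MDL %s\n", object@auc,
              if (is.na(object@mdl)) "not estimated"
              else format(object@mdl)))
})

setMethod("show", "TimeTrace", function(object) {
  cat(sprintf(
    "TimeTrace '%s': %d frames, filter %s (threshold %g, %s)\n",
    object@maskName, length(object@timesS), object@filter@method,
    object@filter@threshold, object@filterMode))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d bands (%g-%g nm), %d frame(s) @ %gs, %d x %d px\n",
    length(object@wavelengths), min(object@wavelengths),
    max(object@wavelengths), object@nFrames, object@frameInterval,
    object@imageShape[1L], object@imageShape[2L]))
  cat(sprintf("  %d cell(s), %d endmember(s), noise %s (scale %g), seed %d\n",
              length(object@cells), length(object@endmemberModels),
              object@noiseModel, object@noiseScale, object@seed))
})
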