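#' Construct a SpectralStack from an array
#'
#' @param data numeric array (band, row, col), nonnegative.
#' @param wavelengths ascending band centers (nm), one per band.
#' @param timeS acquisition time stamp (s) or \code{NA}.
#' @param saturationValue detector full-scale value or \code{NA}.
#' @param corrected whether the data are already flat-response corrected.
#' @return a \linkS4class{SpectralStack}.
#' @export
spectralStack <- function(data, wavelengths, timeS = NA_real_,
                          saturationValue = NA_real_, corrected = FALSE) {
  new("SpectralStack", data = data, wavelengths = as.numeric(wavelengths),
      timeS = as.numeric(timeS),
      saturationValue = as.numeric(saturationValue),
      corrected = corrected)
}

sidecarWavelengthPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".wavelengths.csv")

sidecarMetaPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Write a spectral stack as a multi-page TIFF
#'
#' Pages are written in ascending wavelength order, one per band. A sidecar
#' CSV (\code{<stem>.wavelengths.csv}, header \code{band,wavelength_nm})
#' carries the wavelength axis that plain TIFF cannot, and a JSON sidecar
#' (\code{<stem>.meta.json}) records the storage format, intensity scale,
#' time stamp and saturation value. \code{"uint16"} storage is bit-exact
#' for integer-valued data in [0, 65535]; \code{"float32"} stores
#' peak-scaled 32-bit floats (relative precision ~1e-7) for real-valued
#' corrected data.
#'
#' @param stack a \linkS4class{SpectralStack}.
#' @param path output TIFF path.
#' @param format \code{"uint16"} or \code{"float32"}.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readStack}}
#' @export
writeStack <- function(stack, path, format = c("uint16", "float32")) {
  format <- match.arg(format)
  d <- stack@data
  nb <- dim(d)[1L]
  if (format == "uint16") {
    if (max(d) > 65535 || max(abs(d - round(d))) > 0)
      stop("uint16 storage requires integer data in [0, 65535]; ",
           "use format = 'float32'")
    scale <- 65535
    pages <- lapply(seq_len(nb), function(b) d[b, , ] / 65535)
    bps <- 16L
  } else {
    scale <- max(d, 1e-12)
    pages <- lapply(seq_len(nb), function(b) d[b, , ] / scale)
    bps <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  utils::write.csv(
    data.frame(band = seq_len(nb), wavelength_nm = stack@wavelengths),
    sidecarWavelengthPath(path), row.names = FALSE)
  jsonlite::write_json(
    list(format = format, scale = scale, time_s = stack@timeS,
         saturation_value = stack@saturationValue,
         corrected = stack@corrected),
    sidecarMetaPath(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

readSidecarWavelengths <- function(path) {
  sc <- sidecarWavelengthPath(path)
  if (!file.exists(sc)) return(NULL)
  tab <- utils::read.csv(sc)
  stopIfNot(all(c("band", "wavelength_nm") %in% names(tab)),
            "wavelength sidecar must have columns band,wavelength_nm: ", sc)
  tab$wavelength_nm[order(tab$band)]
}

#' Read a spectral stack from a multi-page TIFF
#'
#' Band order equals page order. Wavelengths are taken (in priority order)
#' from the \code{wavelengths} argument, or the sidecar CSV written by
#' \code{\link{writeStack}}; a stack without either is an error, since a
#' spectral axis is required downstream. Stacks written by
#' \code{\link{writeStack}} round-trip bit-exactly in uint16 mode.
#'
#' @param path TIFF path.
#' @param wavelengths optional numeric override of the wavelength axis.
#' @return a \linkS4class{SpectralStack}.
#' @export
readStack <- function(path, wavelengths = NULL) {
  stopIfNot(file.exists(path), "no such file: ", path)
  meta <- NULL
  mp <- sidecarMetaPath(path)
  if (file.exists(mp)) meta <- jsonlite::read_json(mp)
  isFloat <- !is.null(meta) && identical(meta$format, "float32")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !isFloat)
  if (!is.list(pages)) pages <- list(pages)
  stopIfNot(length(pages) >= 1L, "empty TIFF: ", path)
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
    stop("mismatched page shapes in ", path)
  if (is.null(wavelengths)) wavelengths <- readSidecarWavelengths(path)
  if (is.null(wavelengths))
    stop("no wavelength metadata for ", path,
         ": supply `wavelengths` or a sidecar CSV (band,wavelength_nm)")
  stopIfNot(length(wavelengths) == length(pages),
            "wavelength count does not match page count in ", path)
  scale <- if (isFloat) meta$scale else 1
  d <- array(0, c(length(pages), shp))
  for (b in seq_along(pages)) d[b, , ] <- pages[[b]] * scale
  spectralStack(
    d, wavelengths,
    timeS = if (!is.null(meta) && !is.null(meta$time_s))
      as.numeric(meta$time_s) else NA_real_,
    saturationValue = if (!is.null(meta) && !is.null(meta$saturation_value))
      as.numeric(meta$saturation_value) else NA_real_,
    corrected = isTRUE(meta$corrected))
}

#' Read or write a binary region mask
#'
#' Masks are single-page 8-bit images (PNG or TIFF); any nonzero pixel is
#' inside the region.
#'
#' @param path image path (.png or .tif/.tiff).
#' @return \code{readMask}: logical matrix.
#' @export
readMask <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img != 0
}

#' @rdname readMask
#' @param mask logical matrix.
#' @export
writeMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' Build a flat spectral-response correction profile
#'
#' The correction coefficient vector is the element-wise inverse of the
#' measured illumination power, normalized to a peak value of unity:
#' \code{cc = (1/power) / max(1/power)}. The band with the least power
#' therefore carries coefficient exactly 1, and multiplying a stack by
#' \code{cc} flattens the system's wavelength-dependent excitation
#' response.
#'
#' @param powerTable data.frame with columns \code{wavelength_nm} and
#'   \code{power}, or a numeric power vector (then supply
#'   \code{wavelengths}).
#' @param wavelengths band centers (nm) when \code{powerTable} is a bare
#'   vector.
#' @return a \linkS4class{CorrectionProfile}.
#' @examples
#' buildCorrection(data.frame(wavelength_nm = c(400, 420),
#'                            power = c(2, 1)))
#' @export
buildCorrection <- function(powerTable, wavelengths = NULL) {
  if (is.data.frame(powerTable)) {
    stopIfNot(all(c("wavelength_nm", "power") %in% names(powerTable)),
              "power table needs columns wavelength_nm,power")
    wavelengths <- powerTable$wavelength_nm
    power <- powerTable$power
  } else {
    power <- as.numeric(powerTable)
    stopIfNot(!is.null(wavelengths),
              "supply wavelengths with a bare power vector")
  }
  stopIfNot(all(power > 0), "illumination power must be > 0 at every band")
  inv <- 1 / power
  new("CorrectionProfile", wavelengths = as.numeric(wavelengths),
      power = power, coefficients = inv / max(inv))
}

#' Read an illumination power table CSV
#'
#' @param path CSV with header \code{wavelength_nm,power}.
#' @return a \linkS4class{CorrectionProfile}.
#' @export
readPowerTable <- function(path) buildCorrection(utils::read.csv(path))

#' Per-band mean background from a designated background region
#'
#' @param stack a \linkS4class{SpectralStack}.
#' @param roi logical matrix marking background pixels.
#' @return numeric vector, one mean per band.
#' @export
backgroundFromROI <- function(stack, roi) {
  stopIfNot(any(roi), "background ROI is empty")
  X <- pixelMatrix(stack@data)
  rowMeans(X[, as.vector(roi), drop = FALSE])
}

#' Apply background subtraction and flat spectral-response correction
#'
#' Each band is corrected as \code{max(0, data - background) * coefficient}:
#' the background is subtracted first, negatives are clipped to zero (the
#' abundances being estimated downstream are physically nonnegative), and
#' the result is multiplied by the band's spectral correction coefficient.
#' The output stack is flagged as corrected.
#'
#' @param stack a raw \linkS4class{SpectralStack}.
#' @param profile a \linkS4class{CorrectionProfile} on the same wavelength
#'   grid.
#' @param background per-band scalar vector (e.g. from
#'   \code{\link{backgroundFromROI}}), a same-shape dark
#'   \linkS4class{SpectralStack}, or a single scalar (default 0).
#' @return corrected \linkS4class{SpectralStack}.
#' @export
correctStack <- function(stack, profile, background = 0) {
  stopIfNot(isTRUE(all.equal(stack@wavelengths, profile@wavelengths)),
            "stack and correction profile wavelengths differ")
  d <- stack@data
  nb <- dim(d)[1L]
  if (is(background, "SpectralStack")) background <- background@data
  if (is.array(background) && length(dim(background)) == 3L) {
    stopIfNot(all(dim(background) == dim(d)),
              "dark stack shape does not match")
    d <- d - background
  } else {
    bg <- rep_len(as.numeric(background), nb)
    d <- sweep(d, 1L, bg, "-")
  }
  d <- pmax(d, 0)
  d <- sweep(d, 1L, profile@coefficients, "*")
  spectralStack(d, stack@wavelengths, timeS = stack@timeS,
                saturationValue = stack@saturationValue, corrected = TRUE)
}
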