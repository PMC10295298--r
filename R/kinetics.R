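#' Otsu threshold of a detection map
#'
#' Builds an \code{nBins}-bin histogram over the value range [min, max] and
#' returns the interior bin edge that maximizes the between-class variance
#' omega0 * omega1 * (mu0 - mu1)^2 of the two classes it separates
#' (class 0: values below the edge). Ties are broken toward the lowest
#' threshold.
#'
#' @param map a \linkS4class{DetectionMap} or numeric matrix with at least
#'   two distinct values.
#' @param nBins histogram bin count (default 256, the 8-bit convention).
#' @return numeric(1): the threshold (a bin edge).
#' @export
otsuThreshold <- function(map, nBins = 256L) {
  v <- if (is(map, "DetectionMap")) as.vector(map@values)
       else as.vector(map)
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("otsuThreshold: constant image has no threshold (degenerate)")
  edges <- seq(lo, hi, length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              nBins)
  counts <- tabulate(bin, nBins)
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  w <- cumsum(counts)                       # class-0 count up to bin k
  s <- cumsum(counts * mids)                # class-0 mass up to bin k
  n <- w[nBins]; total <- s[nBins]
  k <- seq_len(nBins - 1L)                  # split after bin k -> edge k+1
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sigma <- rep(-Inf, nBins - 1L)
  mu0 <- s[k][valid] / w0[valid]
  mu1 <- (total - s[k][valid]) / w1[valid]
  sigma[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  best <- which.max(sigma)                  # first max = lowest threshold
  edges[best + 1L]
}

#' Construct a pixel filter
#'
#' @param threshold detector-output threshold.
#' @param method how the threshold was obtained: \code{"none"} (forces
#'   threshold 0; every pixel passes), \code{"tsa"}, \code{"otsu"} or
#'   \code{"manual"}.
#' @param direction passing direction, normally taken from the detection
#'   map: \code{"greater"} for abundance maps, \code{"less"} for angle
#'   maps.
#' @return a \linkS4class{PixelFilter}.
#' @export
pixelFilter <- function(threshold = 0,
                        method = c("manual", "none", "tsa", "otsu"),
                        direction = c("greater", "less")) {
  method <- match.arg(method)
  if (method == "none") threshold <- 0
  new("PixelFilter", threshold = as.numeric(threshold), method = method,
      direction = match.arg(direction))
}

#' Apply a pixel filter to a detection map
#'
#' Returns the binary mask of pixels that pass: strictly above the
#' threshold for \code{direction = "greater"} (abundance maps), strictly
#' below for \code{"less"} (angle maps). A filter with method
#' \code{"none"} passes every pixel.
#'
#' @param map a \linkS4class{DetectionMap} or numeric matrix.
#' @param filter a \linkS4class{PixelFilter}.
#' @return logical matrix.
#' @export
applyFilter <- function(map, filter) {
  v <- if (is(map, "DetectionMap")) map@values else map
  if (filter@method == "none")
    return(matrix(TRUE, nrow(v), ncol(v)))
  if (filter@direction == "greater") v > filter@threshold
  else v < filter@threshold
}

#' Extract a pixel-filtered time trace from detection maps
#'
#' Computes, for every frame, the mean detector output over the pixels of
#' \code{regionMask} that also pass \code{filter}. With
#' \code{filterMode = "per_frame"} the pass mask is recomputed from each
#' frame's map; with \code{"reference_frame"} it is frozen from the map of
#' \code{referenceFrame}. Frames in which no region pixel passes yield
#' \code{NA} (never 0), so sparse frames cannot fabricate signal dips.
#'
#' @param maps list of \linkS4class{DetectionMap}, one per frame, all the
#'   same shape.
#' @param regionMask logical matrix, nonempty: the field of view or a
#'   single-cell region.
#' @param filter a \linkS4class{PixelFilter}.
#' @param filterMode \code{"per_frame"} or \code{"reference_frame"}.
#' @param referenceFrame frame index whose mask is frozen under
#'   \code{"reference_frame"}.
#' @param timesS per-frame time stamps (s); defaults to 0, 1, 2, ... frame
#'   indices if not supplied.
#' @param maskName label stored on the trace.
#' @return a \linkS4class{TimeTrace}.
#' @export
extractTrace <- function(maps, regionMask, filter = pixelFilter(0, "none"),
                         filterMode = c("per_frame", "reference_frame"),
                         referenceFrame = 1L, timesS = NULL,
                         maskName = "region") {
  filterMode <- match.arg(filterMode)
  stopIfNot(length(maps) >= 1L, "extractTrace: no maps")
  stopIfNot(any(regionMask), "extractTrace: empty region")
  shp <- dim(if (is(maps[[1L]], "DetectionMap")) maps[[1L]]@values
             else maps[[1L]])
  stopIfNot(all(dim(regionMask) == shp),
            "extractTrace: region shape does not match maps")
  if (is.null(timesS)) timesS <- seq_along(maps) - 1
  refMask <- if (filterMode == "reference_frame")
    applyFilter(maps[[referenceFrame]], filter) else NULL
  vals <- numeric(length(maps))
  npx <- integer(length(maps))
  for (f in seq_along(maps)) {
    m <- if (is(maps[[f]], "DetectionMap")) maps[[f]]@values
         else maps[[f]]
    stopIfNot(all(dim(m) == shp), "extractTrace: frame shape mismatch")
    pass <- if (filterMode == "per_frame") applyFilter(maps[[f]], filter)
            else refMask
    sel <- regionMask & pass
    npx[f] <- sum(sel)
    vals[f] <- if (npx[f] > 0) mean(m[sel]) else NA_real_
  }
  new("TimeTrace", timesS = as.numeric(timesS), values = vals,
      nPixels = npx, maskName = maskName, filter = filter,
      filterMode = filterMode)
}

#' Convert a time trace to a data.frame / write it as CSV
#'
#' @param trace a \linkS4class{TimeTrace}.
#' @return \code{traceToFrame}: data.frame with columns \code{time_s},
#'   \code{mean}, \code{n_pixels}.
#' @export
traceToFrame <- function(trace) {
  data.frame(time_s = trace@timesS, mean = trace@values,
             n_pixels = trace@nPixels)
}

#' @rdname traceToFrame
#' @param path CSV path.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(traceToFrame(trace), path, row.names = FALSE)
  invisible(path)
}
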