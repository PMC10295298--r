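#' @import methods
NULL

.EPS <- 1e-9

#' SpectralStack: one excitation-scanned spectral image
#'
#' Container for a single hyperspectral image cube acquired by scanning the
#' excitation wavelength: a nonnegative 3-D array indexed (band, row, col)
#' in arbitrary intensity units, with one excitation-band center wavelength
#' (nm) per band in strictly ascending order. A time-lapse acquisition is an
#' ordered list of these, one per time point.
#'
#' @slot data numeric array, dim (bands, rows, cols), all values >= 0.
#' @slot wavelengths numeric, nm per band, strictly increasing.
#' @slot timeS numeric(1), acquisition time stamp in seconds, or \code{NA}.
#' @slot saturationValue numeric(1), detector full-scale value, or \code{NA}.
#' @slot corrected logical(1), \code{TRUE} once flat spectral-response
#'   correction has been applied (see \code{\link{correctStack}}).
#'
#' @seealso \code{\link{readStack}}, \code{\link{correctStack}}
#' @export
setClass("SpectralStack",
  representation(
    data = "array",
    wavelengths = "numeric",
    timeS = "numeric",
    saturationValue = "numeric",
    corrected = "logical"
  ),
  prototype(timeS = NA_real_, saturationValue = NA_real_, corrected = FALSE)
)

setValidity("SpectralStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (band, row, col)")
  if (dim(d)[1L] != length(object@wavelengths))
    return("number of bands must equal length(wavelengths)")
  if (length(object@wavelengths) >= 2L &&
      any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(!is.finite(d)))
    return("data must be finite")
  if (min(d) < 0)
    return("data must be nonnegative")
  if (length(object@timeS) != 1L || length(object@saturationValue) != 1L ||
      length(object@corrected) != 1L)
    return("timeS, saturationValue and corrected must be scalars")
  TRUE
})

#' CorrectionProfile: flat spectral-response correction coefficients
#'
#' Per-band correction coefficients derived from a measured illumination
#' power-vs-wavelength table. The coefficient vector is the element-wise
#' inverse of the power vector, normalized to a peak value of unity, so the
#' band with the least illumination power carries coefficient exactly 1.
#'
#' @slot wavelengths numeric, nm per band, strictly increasing.
#' @slot power numeric, measured illumination power per band (> 0, arbitrary
#'   power units).
#' @slot coefficients numeric, dimensionless correction coefficients with
#'   \code{max(coefficients) == 1}.
#'
#' @seealso \code{\link{buildCorrection}}, \code{\link{correctStack}}
#' @export
setClass("CorrectionProfile",
  representation(
    wavelengths = "numeric",
    power = "numeric",
    coefficients = "numeric"
  )
)

setValidity("CorrectionProfile", function(object) {
  n <- length(object@wavelengths)
  if (length(object@power) != n || length(object@coefficients) != n)
    return("wavelengths, power and coefficients must have equal length")
  if (n >= 2L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(object@power <= 0))
    return("power must be strictly positive at every band")
  if (abs(max(object@coefficients) - 1) > .EPS)
    return("coefficients must be normalized to a peak value of 1")
  expec <- (1 / object@power) / max(1 / object@power)
  if (max(abs(expec - object@coefficients)) > 1e-6)
    return("coefficients must be proportional to 1/power")
  TRUE
})

#' SpectralLibrary: peak-normalized endmember spectra
#'
#' A matrix of pure endmember excitation spectra (one row per endmember, one
#' column per band), each row nonnegative and peak-normalized so its maximum
#' is exactly 1, with unique endmember names.
#'
#' @slot names character, unique endmember labels, one per row.
#' @slot spectra numeric matrix (endmembers x bands), entries >= 0, each row
#'   maximum exactly 1.
#' @slot wavelengths numeric, nm per band, strictly increasing.
#'
#' @seealso \code{\link{makeLibrary}}, \code{\link{assembleLibrary}},
#'   \code{\link{extractReference}}
#' @export
setClass("SpectralLibrary",
  representation(
    names = "character",
    spectra = "matrix",
    wavelengths = "numeric"
  )
)

setValidity("SpectralLibrary", function(object) {
  s <- object@spectra
  if (nrow(s) != length(object@names))
    return("one name per spectrum required")
  if (ncol(s) != length(object@wavelengths))
    return("one wavelength per band required")
  if (anyDuplicated(object@names))
    return("endmember names must be unique")
  if (length(object@wavelengths) >= 2L &&
      any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(s < 0))
    return("library spectra must be nonnegative")
  if (any(abs(apply(s, 1L, max) - 1) > 1e-7))
    return("every spectrum must be peak-normalized to a maximum of 1")
  TRUE
})

#' DetectionMap: per-endmember scalar detector output
#'
#' The scalar image a pixel-wise spectral detector produces for one
#' endmember: an abundance image for LU, CEM and MF, or a spectral-angle
#' image (radians, in [0, pi]) for SAM. \code{positiveDirection} records
#' which side of a threshold counts as a positive detection: \code{"greater"}
#' for abundance maps, \code{"less"} for angle maps (small angle = similar
#' spectrum).
#'
#' @slot values numeric matrix (row, col).
#' @slot endmember character(1), the target endmember name.
#' @slot kind \code{"abundance"} or \code{"angle"}.
#' @slot algorithm one of \code{"LU"}, \code{"SAM"}, \code{"CEM"}, \code{"MF"}.
#' @slot positiveDirection \code{"greater"} or \code{"less"}.
#'
#' @export
setClass("DetectionMap",
  representation(
    values = "matrix",
    endmember = "character",
    kind = "character",
    algorithm = "character",
    positiveDirection = "character"
  )
)

setValidity("DetectionMap", function(object) {
  if (!object@kind %in% c("abundance", "angle"))
    return("kind must be 'abundance' or 'angle'")
  if (!object@algorithm %in% c("LU", "SAM", "CEM", "MF"))
    return("algorithm must be one of LU, SAM, CEM, MF")
  if (!object@positiveDirection %in% c("greater", "less"))
    return("positiveDirection must be 'greater' or 'less'")
  if ((object@kind == "angle") != (object@positiveDirection == "less"))
    return("positiveDirection must be 'less' exactly for angle maps")
  if (object@kind == "angle") {
    v <- object@values
    if (any(v < -.EPS | v > pi + .EPS))
      return("angle maps must lie in [0, pi]")
  }
  TRUE
})

#' UnmixResult: full linear-unmixing output
#'
#' One \linkS4class{DetectionMap} per library endmember plus the per-pixel
#' root-mean-square residual (over bands) of the non-negatively constrained
#' least-squares fit.
#'
#' @slot maps list of \linkS4class{DetectionMap}, named by endmember.
#' @slot rmsError numeric matrix (row, col), >= 0.
#'
#' @seealso \code{\link{unmixLU}}
#' @export
setClass("UnmixResult",
  representation(maps = "list", rmsError = "matrix")
)

setValidity("UnmixResult", function(object) {
  if (!all(vapply(object@maps, is, TRUE, "DetectionMap")))
    return("maps must be DetectionMap objects")
  if (length(object@maps) && min(object@rmsError) < -.EPS)
    return("rmsError must be nonnegative")
  TRUE
})

#' CEMFilter: constrained energy minimization operator
#'
#' The finite impulse response vector of the CEM detector together with the
#' sample correlation matrix it was derived from. The operator satisfies the
#' unity-gain constraint \code{sum(operator * target spectrum) == 1}.
#'
#' @slot operator numeric, length = number of bands.
#' @slot correlation numeric matrix (bands x bands), symmetric PSD sample
#'   correlation matrix of the image's pixel spectra.
#' @slot target character(1), target endmember name.
#' @slot targetSpectrum numeric, the peak-normalized target spectrum.
#'
#' @seealso \code{\link{cemBuild}}, \code{\link{cemApply}}
#' @export
setClass("CEMFilter",
  representation(
    operator = "numeric",
    correlation = "matrix",
    target = "character",
    targetSpectrum = "numeric"
  )
)

setValidity("CEMFilter", function(object) {
  b <- length(object@operator)
  if (!all(dim(object@correlation) == c(b, b)))
    return("correlation must be B x B")
  if (length(object@targetSpectrum) != b)
    return("targetSpectrum length must match operator")
  if (max(abs(object@correlation - t(object@correlation))) > 1e-8)
    return("correlation matrix must be symmetric")
  if (abs(sum(object@operator * object@targetSpectrum) - 1) > 1e-6)
    return("operator must have unity gain on the target spectrum")
  TRUE
})

#' MFOperator: matched-filter rejection operator
#'
#' The orthogonal-subspace rejection operator \code{P = I - U U#} built from
#' the non-target library spectra (columns of \code{U}), its pseudo-inverse
#' \code{U# = (U'U)^-1 U'}, and the filter vector \code{q = r' P} for the
#' target spectrum r. P is a symmetric idempotent projector that annihilates
#' every background spectrum.
#'
#' @slot rejection numeric matrix (bands x bands), the projector P.
#' @slot pseudoInverse numeric matrix, \code{U#}.
#' @slot filterVector numeric, q.
#' @slot background numeric matrix (bands x non-target endmembers), U.
#' @slot target character(1), target endmember name.
#' @slot normalized logical(1), whether map values are divided by
#'   \code{sum(q * r)}.
#'
#' @seealso \code{\link{mfBuild}}, \code{\link{mfApply}}
#' @export
setClass("MFOperator",
  representation(
    rejection = "matrix",
    pseudoInverse = "matrix",
    filterVector = "numeric",
    background = "matrix",
    target = "character",
    targetSpectrum = "numeric",
    normalized = "logical"
  )
)

setValidity("MFOperator", function(object) {
  P <- object@rejection
  if (max(abs(P - t(P))) > 1e-8) return("rejection operator must be symmetric")
  if (max(abs(P %*% P - P)) > 1e-7)
    return("rejection operator must be idempotent")
  if (ncol(object@background) > 0 &&
      max(abs(P %*% object@background)) > 1e-7)
    return("rejection operator must annihilate background spectra")
  TRUE
})

#' TSAConfig: theoretical sensitivity analysis configuration
#'
#' Parameters of the injection experiment: the ROI whose pixels receive
#' added target signal, the injection scalars, the fixed injection level for
#' the ROC threshold sweep, the positive-pixel threshold, the ROC threshold
#' grid and the detector under test. Defaults follow the analysis settings
#' used for an excitation-scanning Ca2+ study: injection increments of 1
#' over 0-30, ROC scale factor 5, positive-pixel threshold 15 (0.98 radians
#' for SAM), and ROC thresholds 0-50 (0-1.8 radians for SAM).
#'
#' @slot roi logical matrix, injection region (TRUE = inside).
#' @slot target character(1), target endmember name.
#' @slot aGrid numeric, ascending injection scalars, >= 0, containing 0.
#' @slot rocScale numeric(1), injection level for the ROC sweep.
#' @slot tppcThreshold numeric(1), detection threshold for the positive-pixel
#'   curve.
#' @slot thresholdGrid numeric, ascending thresholds for the ROC sweep.
#' @slot detector one of \code{"LU"}, \code{"SAM"}, \code{"CEM"}, \code{"MF"}.
#'
#' @seealso \code{\link{tsaConfig}}, \code{\link{runTSA}}
#' @export
setClass("TSAConfig",
  representation(
    roi = "matrix",
    target = "character",
    aGrid = "numeric",
    rocScale = "numeric",
    tppcThreshold = "numeric",
    thresholdGrid = "numeric",
    detector = "character"
  )
)

setValidity("TSAConfig", function(object) {
  if (!is.logical(object@roi)) return("roi must be a logical matrix")
  if (!object@detector %in% c("LU", "SAM", "CEM", "MF"))
    return("detector must be one of LU, SAM, CEM, MF")
  if (any(object@aGrid < 0)) return("aGrid must be nonnegative")
  if (is.unsorted(object@aGrid, strictly = TRUE))
    return("aGrid must be strictly increasing")
  if (!any(object@aGrid == 0)) return("aGrid must contain 0")
  if (object@rocScale < 0) return("rocScale must be nonnegative")
  if (!length(object@thresholdGrid)) return("thresholdGrid must be nonempty")
  if (is.unsorted(object@thresholdGrid, strictly = TRUE))
    return("thresholdGrid must be strictly increasing")
  TRUE
})

#' TSAResult: theoretical sensitivity analysis output
#'
#' Holds the three performance curves for one detector/target pair: the
#' theoretical sensitivity curve (detector output over the ROI vs the
#' injected amount, with a linear fit), the thresholded positive pixel curve
#' (whole-image positive count vs injected amount), the ROC curve at a fixed
#' injection level with its AUC, and the estimated minimum detectable limit.
#'
#' @slot tsc data.frame with columns \code{a}, \code{mean}, \code{sd}.
#' @slot tscValues list of numeric vectors, the full ROI output distribution
#'   at each injection level.
#' @slot fit named numeric: \code{slope}, \code{intercept}, \code{r2} of the
#'   ordinary least-squares line through (a, mean).
#' @slot tppc data.frame with columns \code{a}, \code{count}.
#' @slot roc data.frame with columns \code{threshold}, \code{fpr}, \code{tpr}
#'   (the appended (0,0) and (1,1) endpoints carry \code{NA} thresholds).
#' @slot auc numeric(1) in [0, 1], trapezoid area under the ROC curve.
#' @slot mdl numeric(1), minimum detectable limit in detector-output units
#'   (\code{NA} until estimated).
#' @slot detector character(1); @slot target character(1).
#'
#' @seealso \code{\link{runTSA}}
#' @export
setClass("TSAResult",
  representation(
    tsc = "data.frame",
    tscValues = "list",
    fit = "numeric",
    tppc = "data.frame",
    roc = "data.frame",
    auc = "numeric",
    mdl = "numeric",
    detector = "character",
    target = "character"
  ),
  prototype(auc = NA_real_, mdl = NA_real_)
)

#' PixelFilter: detection-threshold pixel filter
#'
#' A threshold on detector output used to reject pixels below a minimum
#' detectable limit before trace quantification. \code{method} records how
#' the threshold was obtained: \code{"none"} (threshold 0, all pixels pass),
#' \code{"tsa"} (from the theoretical sensitivity analysis), \code{"otsu"},
#' or \code{"manual"}. \code{direction} mirrors the map's positive
#' direction: abundance maps pass strictly above the threshold, angle maps
#' strictly below.
#'
#' @slot threshold numeric(1), detector-output units.
#' @slot method one of \code{"none"}, \code{"tsa"}, \code{"otsu"},
#'   \code{"manual"}.
#' @slot direction \code{"greater"} or \code{"less"}.
#'
#' @seealso \code{\link{pixelFilter}}, \code{\link{applyFilter}}
#' @export
setClass("PixelFilter",
  representation(
    threshold = "numeric",
    method = "character",
    direction = "character"
  )
)

setValidity("PixelFilter", function(object) {
  if (!object@method %in% c("none", "tsa", "otsu", "manual"))
    return("method must be one of none, tsa, otsu, manual")
  if (!object@direction %in% c("greater", "less"))
    return("direction must be 'greater' or 'less'")
  if (object@method == "none" && object@threshold != 0)
    return("method 'none' requires threshold 0")
  TRUE
})

#' TimeTrace: signal-vs-time series for a masked region
#'
#' Mean detector output per frame over the pixels of a region mask that also
#' pass a \linkS4class{PixelFilter}, together with the per-frame count of
#' passing pixels. Frames in which no pixel passes carry \code{NA}, never 0,
#' so that empty frames cannot masquerade as signal dips.
#'
#' @slot timesS numeric, frame time stamps (s).
#' @slot values numeric, per-frame filtered region mean (NA if no pixel
#'   passes).
#' @slot nPixels integer, passing-pixel count per frame.
#' @slot maskName character(1), region label.
#' @slot filter the \linkS4class{PixelFilter} applied.
#' @slot filterMode \code{"per_frame"} or \code{"reference_frame"}.
#'
#' @seealso \code{\link{extractTrace}}
#' @export
setClass("TimeTrace",
  representation(
    timesS = "numeric",
    values = "numeric",
    nPixels = "integer",
    maskName = "character",
    filter = "PixelFilter",
    filterMode = "character"
  )
)

setValidity("TimeTrace", function(object) {
  n <- length(object@timesS)
  if (length(object@values) != n || length(object@nPixels) != n)
    return("timesS, values and nPixels must have equal length")
  if (any(object@nPixels < 0)) return("nPixels must be nonnegative")
  if (any(object@nPixels == 0 & !is.na(object@values)))
    return("frames with zero passing pixels must carry NA values")
  if (!object@filterMode %in% c("per_frame", "reference_frame"))
    return("filterMode must be 'per_frame' or 'reference_frame'")
  TRUE
})

## ---- synthetic-scene classes -------------------------------------------

#' SpectrumModel: parametric endmember excitation spectrum
#'
#' A truncated-Gaussian excitation spectrum plus a flat baseline fraction,
#' evaluated on a wavelength grid and peak-normalized. The broad cellular
#' autofluorescence endmember is modeled with a large width and baseline;
#' labels with excitation peaks outside the scanned range (e.g. a Ca2+
#' indicator peaking near 495 nm on a 360-480 nm scan) yield monotonically
#' rising spectra that max out at the last scanned band.
#'
#' @slot name character(1), endmember label.
#' @slot peakNm numeric(1), excitation peak wavelength (nm); may lie outside
#'   the scanned grid.
#' @slot widthNm numeric(1), Gaussian sigma (nm), > 0.
#' @slot baseline numeric(1) in [0, 1], flat additive component as a
#'   fraction of the Gaussian peak.
#'
#' @seealso \code{\link{spectrumModel}}, \code{\link{makeLibrary}}
#' @export
setClass("SpectrumModel",
  representation(
    name = "character",
    peakNm = "numeric",
    widthNm = "numeric",
    baseline = "numeric"
  )
)

setValidity("SpectrumModel", function(object) {
  if (object@widthNm <= 0) return("widthNm must be positive")
  if (object@baseline < 0 || object@baseline > 1)
    return("baseline must lie in [0, 1]")
  TRUE
})

#' CellSpec: geometry and kinetics of one synthetic cell
#'
#' An elliptical cell body containing an elliptical nucleus, with constant
#' nuclear-label and autofluorescence abundances and a Ca2+ abundance that
#' follows a baseline plus an optional agonist-triggered transient:
#' step onset at \code{onset} seconds, exponential decay with time constant
#' \code{decay}, and an optional superimposed sinusoidal oscillation of
#' period \code{period} seconds.
#'
#' @slot center numeric(2), (row, col) of the cell center (pixels).
#' @slot bodyAxes numeric(2), ellipse semi-axes (row, col) in pixels.
#' @slot nucleusAxes numeric(2), nucleus semi-axes, each <= the body axis.
#' @slot caBaseline numeric(1) >= 0, resting Ca2+-label abundance.
#' @slot caTransient numeric(4): \code{onset} (s), \code{amplitude},
#'   \code{decay} (s), \code{period} (s, \code{NA} = no oscillation).
#'   Amplitude 0 disables the transient.
#' @slot nucLevel numeric(1) >= 0, nuclear-label abundance inside the
#'   nucleus.
#' @slot afLevel numeric(1) >= 0, autofluorescence abundance over the body
#'   (the blue-weighted, NAD(P)H-like component when the scene models
#'   autofluorescence as two sub-components).
#' @slot af2Level numeric(1) >= 0, abundance of the second (green-weighted,
#'   flavin-like) autofluorescence sub-component; 0 when unused. Varying
#'   the af:af2 ratio across cells emulates the cell-to-cell spectral
#'   variability of real autofluorescence that a single pooled library
#'   reference cannot capture.
#'
#' @seealso \code{\link{cellSpec}}, \code{\link{renderScene}}
#' @export
setClass("CellSpec",
  representation(
    center = "numeric",
    bodyAxes = "numeric",
    nucleusAxes = "numeric",
    caBaseline = "numeric",
    caTransient = "numeric",
    nucLevel = "numeric",
    afLevel = "numeric",
    af2Level = "numeric"
  ),
  prototype(af2Level = 0)
)

setValidity("CellSpec", function(object) {
  if (length(object@center) != 2L || length(object@bodyAxes) != 2L ||
      length(object@nucleusAxes) != 2L)
    return("center, bodyAxes and nucleusAxes must have length 2")
  if (any(object@bodyAxes <= 0)) return("bodyAxes must be positive")
  if (any(object@nucleusAxes > object@bodyAxes))
    return("nucleus ellipse must be contained in the body ellipse")
  if (object@caBaseline < 0 || object@nucLevel < 0 ||
      object@afLevel < 0 || object@af2Level < 0)
    return("abundance levels must be nonnegative")
  if (length(object@caTransient) != 4L)
    return("caTransient must be (onset, amplitude, decay, period)")
  if (object@caTransient[2L] < 0)
    return("transient amplitude must be nonnegative")
  if (object@caTransient[2L] > 0 && object@caTransient[3L] <= 0)
    return("transient decay constant must be positive")
  TRUE
})

#' SyntheticScene: full specification of a synthetic acquisition
#'
#' Everything needed to render a time-lapse excitation-scanning acquisition
#' with known ground truth: the wavelength grid, frame timing, image shape,
#' the cells, the endmember spectrum models, the noise model and a seed that
#' fully determines the output.
#'
#' @slot wavelengths numeric, excitation-band centers (nm), strictly
#'   increasing.
#' @slot frameInterval numeric(1), seconds between frames.
#' @slot nFrames integer(1) >= 1.
#' @slot imageShape integer(2), (rows, cols).
#' @slot cells list of \linkS4class{CellSpec}.
#' @slot endmemberModels list of \linkS4class{SpectrumModel}; must contain
#'   models named for every abundance channel used (\code{"Ca"},
#'   \code{"Nuc"}, \code{"AF"} by convention of the level slots).
#' @slot roles named character with names \code{nuc}, \code{ca}, \code{af}
#'   (and optionally \code{af2} for a second autofluorescence
#'   sub-component), mapping each abundance channel of
#'   \linkS4class{CellSpec} to an endmember model name.
#' @slot bgLevel numeric(1) >= 0, diffuse background autofluorescence
#'   abundance present at every pixel (extracellular media fluorescence and
#'   stray light; a widefield image has no truly signal-free pixels).
#' @slot noiseModel \code{"none"}, \code{"gaussian"} or \code{"poisson"}.
#' @slot noiseScale numeric(1) >= 0: Gaussian sd, or the Poisson gain
#'   (intensity units per detected count; shot noise sd = sqrt(gain *
#'   intensity)).
#' @slot seed integer(1), determines all randomness.
#'
#' @seealso \code{\link{syntheticScene}}, \code{\link{renderScene}},
#'   \code{\link{exampleScene}}
#' @export
setClass("SyntheticScene",
  representation(
    wavelengths = "numeric",
    frameInterval = "numeric",
    nFrames = "integer",
    imageShape = "integer",
    cells = "list",
    endmemberModels = "list",
    roles = "character",
    bgLevel = "numeric",
    noiseModel = "character",
    noiseScale = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticScene", function(object) {
  if (length(object@wavelengths) < 1L ||
      (length(object@wavelengths) >= 2L &&
       any(diff(object@wavelengths) <= 0)))
    return("wavelengths must be nonempty and strictly increasing")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    return("imageShape must be two positive integers")
  if (!object@noiseModel %in% c("none", "gaussian", "poisson"))
    return("noiseModel must be none, gaussian or poisson")
  if (object@noiseScale < 0) return("noise scale must be nonnegative")
  if (length(object@bgLevel) != 1L || object@bgLevel < 0)
    return("bgLevel must be a nonnegative scalar")
  if (!all(vapply(object@cells, is, TRUE, "CellSpec")))
    return("cells must be CellSpec objects")
  if (!all(vapply(object@endmemberModels, is, TRUE, "SpectrumModel")))
    return("endmemberModels must be SpectrumModel objects")
  modelNames <- vapply(object@endmemberModels, function(m) m@name, "")
  if (!all(c("nuc", "ca", "af") %in% names(object@roles)))
    return("roles must carry names nuc, ca and af")
  if (!all(object@roles %in% modelNames))
    return("every role must name an endmember model")
  if (!"af2" %in% names(object@roles) &&
      any(vapply(object@cells, function(cl) cl@af2Level, 0) > 0))
    return("cells use af2Level but the scene has no af2 role")
  for (cl in object@cells) {
    if (cl@center[1L] - cl@bodyAxes[1L] < 0.5 ||
        cl@center[1L] + cl@bodyAxes[1L] > object@imageShape[1L] + 0.5 ||
        cl@center[2L] - cl@bodyAxes[2L] < 0.5 ||
        cl@center[2L] + cl@bodyAxes[2L] > object@imageShape[2L] + 0.5)
      return("every cell must lie within imageShape")
  }
  TRUE
})

#' GroundTruth: known abundances behind a rendered scene
#'
#' The per-endmember, per-frame abundance images, the per-cell body masks
#' and the spectral library used for mixing. For a noiseless render, the
#' stack equals the library-weighted sum of the abundance maps exactly at
#' every pixel, band and frame.
#'
#' @slot abundances named list (one per endmember) of 3-D arrays
#'   (row, col, frame).
#' @slot masks list of logical matrices, one body mask per cell.
#' @slot library the \linkS4class{SpectralLibrary} used for mixing.
#'
#' @seealso \code{\link{renderScene}}
#' @export
setClass("GroundTruth",
  representation(abundances = "list", masks = "list",
                 library = "SpectralLibrary")
)
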