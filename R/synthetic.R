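#' Construct a parametric endmember spectrum model
#'
#' @param name endmember label.
#' @param peakNm excitation peak wavelength (nm); may lie beyond the scanned
#'   range, in which case the evaluated spectrum is monotone over the grid
#'   and peaks at the nearest scanned band.
#' @param widthNm Gaussian sigma (nm), > 0.
#' @param baseline flat additive fraction in [0, 1]; large widths plus a
#'   baseline mimic broad cellular autofluorescence.
#' @return a \linkS4class{SpectrumModel}.
#' @examples
#' spectrumModel("Cal520", peakNm = 495, widthNm = 40)
#' @export
spectrumModel <- function(name, peakNm, widthNm, baseline = 0) {
  new("SpectrumModel", name = as.character(name), peakNm = as.numeric(peakNm),
      widthNm = as.numeric(widthNm), baseline = as.numeric(baseline))
}

# Evaluate one model on a wavelength grid (unnormalized, nonnegative).
evalSpectrumModel <- function(model, wavelengths) {
  g <- exp(-(wavelengths - model@peakNm)^2 / (2 * model@widthNm^2))
  pmax(g + model@baseline, 0)
}

#' Build a peak-normalized spectral library from spectrum models
#'
#' Evaluates each model on the wavelength grid and normalizes each spectrum
#' to a peak value of unity, preserving model order.
#'
#' @param models list of \linkS4class{SpectrumModel} (at least one).
#' @param wavelengths numeric, ascending band centers (nm), nonempty.
#' @return a \linkS4class{SpectralLibrary}.
#' @examples
#' wl <- seq(360, 480, by = 5)
#' lib <- makeLibrary(list(spectrumModel("AF", 420, 120, 0.35)), wl)
#' @export
makeLibrary <- function(models, wavelengths) {
  stopIfNot(length(models) >= 1L, "makeLibrary: at least one model required")
  stopIfNot(length(wavelengths) >= 1L,
            "makeLibrary: wavelengths must be nonempty")
  if (inherits(models, "SpectrumModel")) models <- list(models)
  spec <- t(vapply(models, function(m)
    peakNormalize(evalSpectrumModel(m, wavelengths)),
    numeric(length(wavelengths))))
  new("SpectralLibrary",
      names = vapply(models, function(m) m@name, ""),
      spectra = spec, wavelengths = as.numeric(wavelengths))
}

#' Construct a synthetic cell specification
#'
#' @param center numeric(2), (row, col) center in pixels.
#' @param bodyAxes numeric(2), body ellipse semi-axes (pixels).
#' @param nucleusAxes numeric(2), nucleus semi-axes (pixels); must fit
#'   inside the body.
#' @param caBaseline resting Ca2+-label abundance (>= 0).
#' @param caTransient numeric(4): onset time (s), amplitude, exponential
#'   decay constant (s), oscillation period (s, \code{NA} for none). Use
#'   amplitude 0 for a quiescent cell.
#' @param nucLevel nuclear-label abundance inside the nucleus.
#' @param af2Level abundance of the second (flavin-like) autofluorescence
#'   sub-component for scenes modeling heterogeneous autofluorescence
#'   (default 0).
#' @param afLevel autofluorescence abundance over the body.
#' @return a \linkS4class{CellSpec}.
#' @export
cellSpec <- function(center, bodyAxes, nucleusAxes = bodyAxes / 3,
                     caBaseline = 0,
                     caTransient = c(onset = 0, amplitude = 0,
                                     decay = 1, period = NA),
                     nucLevel = 0, afLevel = 0, af2Level = 0) {
  tr <- as.numeric(caTransient)
  names(tr) <- c("onset", "amplitude", "decay", "period")
  new("CellSpec", center = as.numeric(center),
      bodyAxes = as.numeric(bodyAxes),
      nucleusAxes = as.numeric(nucleusAxes),
      caBaseline = as.numeric(caBaseline), caTransient = tr,
      nucLevel = as.numeric(nucLevel), afLevel = as.numeric(afLevel),
      af2Level = as.numeric(af2Level))
}

#' Construct a synthetic acquisition scene
#'
#' @param wavelengths ascending band centers (nm).
#' @param frameInterval seconds between frames.
#' @param nFrames number of time points (>= 1).
#' @param imageShape integer(2), (rows, cols).
#' @param cells list of \linkS4class{CellSpec}.
#' @param endmemberModels list of \linkS4class{SpectrumModel}.
#' @param roles named character mapping the \code{nuc}, \code{ca} and
#'   \code{af} abundance channels to model names; defaults to the first
#'   three models in that order.
#' @param bgLevel diffuse background autofluorescence abundance added at
#'   every pixel (default 0).
#' @param noiseModel \code{"none"}, \code{"gaussian"} or \code{"poisson"}.
#' @param noiseScale Gaussian sd, or Poisson gain (intensity units per
#'   count), >= 0.
#' @param seed integer seed; fully determines the rendered output.
#' @return a \linkS4class{SyntheticScene}.
#' @seealso \code{\link{renderScene}}, \code{\link{exampleScene}}
#' @export
syntheticScene <- function(wavelengths, frameInterval = 30, nFrames = 1L,
                           imageShape = c(64L, 64L), cells = list(),
                           endmemberModels,
                           roles = NULL, bgLevel = 0,
                           noiseModel = c("none", "gaussian", "poisson"),
                           noiseScale = 0, seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopIfNot(noiseScale >= 0, "syntheticScene: noise scale must be >= 0")
  if (is.null(roles)) {
    stopIfNot(length(endmemberModels) >= 3L,
              "syntheticScene: default roles need at least three models")
    nm <- vapply(endmemberModels, function(m) m@name, "")
    roles <- c(nuc = nm[1L], ca = nm[2L], af = nm[3L])
  }
  new("SyntheticScene", wavelengths = as.numeric(wavelengths),
      frameInterval = as.numeric(frameInterval),
      nFrames = as.integer(nFrames),
      imageShape = as.integer(imageShape), cells = cells,
      endmemberModels = endmemberModels, roles = roles,
      bgLevel = as.numeric(bgLevel),
      noiseModel = noiseModel, noiseScale = as.numeric(noiseScale),
      seed = as.integer(seed))
}

# Ca2+ abundance of one cell at frame times t (s): baseline plus a
# step-onset transient with exponential decay and optional oscillation.
caLevelAt <- function(cell, t) {
  tr <- cell@caTransient
  lev <- rep(cell@caBaseline, length(t))
  if (tr[["amplitude"]] > 0) {
    dt <- t - tr[["onset"]]
    on <- dt >= 0
    env <- tr[["amplitude"]] * exp(-dt[on] / tr[["decay"]])
    if (!is.na(tr[["period"]]) && tr[["period"]] > 0)
      env <- env * 0.5 * (1 + sin(2 * pi * dt[on] / tr[["period"]]))
    lev[on] <- lev[on] + env
  }
  lev
}

#' Render a synthetic scene into spectral stacks plus ground truth
#'
#' Builds the peak-normalized library from the scene's endmember models,
#' composes per-endmember abundance images for every frame (nuclear label in
#' the nucleus, Ca2+ label and autofluorescence over the cell body, Ca2+
#' level following each cell's transient), mixes them through the linear
#' mixing model (each pixel spectrum is the abundance-weighted sum of the
#' library spectra), and finally applies the scene's noise model per pixel
#' and band. The scene seed fully determines the output.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return list with elements \code{stacks} (list of
#'   \linkS4class{SpectralStack}, one per frame, marked corrected) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' sc <- exampleScene("tiny")
#' r <- renderScene(sc)
#' length(r$stacks)
#' @export
renderScene <- function(scene) {
  validObject(scene)
  lib <- makeLibrary(scene@endmemberModels, scene@wavelengths)
  shape <- scene@imageShape
  nF <- scene@nFrames
  nPx <- prod(shape)
  times <- (seq_len(nF) - 1L) * scene@frameInterval

  abund <- setNames(
    lapply(lib@names, function(n) array(0, c(shape, nF))),
    lib@names)
  if (scene@bgLevel > 0)
    abund[[scene@roles[["af"]]]][] <- scene@bgLevel
  masks <- vector("list", length(scene@cells))
  for (i in seq_along(scene@cells)) {
    cl <- scene@cells[[i]]
    body <- ellipseMask(shape, cl@center, cl@bodyAxes)
    nuc <- ellipseMask(shape, cl@center, cl@nucleusAxes)
    masks[[i]] <- body
    ca <- caLevelAt(cl, times)
    for (f in seq_len(nF)) {
      sl <- abund[[scene@roles[["ca"]]]][, , f]
      sl[body] <- sl[body] + ca[f]
      abund[[scene@roles[["ca"]]]][, , f] <- sl
      sl <- abund[[scene@roles[["nuc"]]]][, , f]
      sl[nuc] <- sl[nuc] + cl@nucLevel
      abund[[scene@roles[["nuc"]]]][, , f] <- sl
      sl <- abund[[scene@roles[["af"]]]][, , f]
      sl[body] <- sl[body] + cl@afLevel
      abund[[scene@roles[["af"]]]][, , f] <- sl
      if (cl@af2Level > 0) {
        sl <- abund[[scene@roles[["af2"]]]][, , f]
        sl[body] <- sl[body] + cl@af2Level
        abund[[scene@roles[["af2"]]]][, , f] <- sl
      }
    }
  }

  S <- t(lib@spectra)                      # B x m
  stacks <- withSeed(scene@seed, lapply(seq_len(nF), function(f) {
    A <- vapply(lib@names, function(n) as.vector(abund[[n]][, , f]),
                numeric(nPx))              # N x m
    X <- S %*% t(A)                        # B x N
    X <- applyNoise(X, scene@noiseModel, scene@noiseScale)
    new("SpectralStack",
        data = array(X, c(length(scene@wavelengths), shape)),
        wavelengths = scene@wavelengths, timeS = times[f],
        saturationValue = NA_real_, corrected = TRUE)
  }))

  list(stacks = stacks,
       truth = new("GroundTruth", abundances = abund, masks = masks,
                   library = lib))
}

# Per-pixel, per-band noise applied after mixing. Poisson emulates
# shot-noise-limited detection: intensity = gain * Poisson(intensity/gain).
applyNoise <- function(X, model, scale) {
  if (model == "none" || scale == 0) return(X)
  if (model == "gaussian")
    return(pmax(X + stats::rnorm(length(X), sd = scale), 0))
  array(scale * stats::rpois(length(X), X / scale), dim(X))
}
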