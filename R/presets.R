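#' Built-in endmember spectrum models
#'
#' Three parametric excitation spectra emulating the labels of a
#' dual-labeled airway smooth muscle Ca2+ experiment on a 360-480 nm
#' excitation scan: a nuclear label peaking at 360 nm, a Ca2+ indicator
#' whose excitation peak (~495 nm) lies beyond the scanned range so its
#' spectrum rises monotonically and maxes out at 480 nm, and a broad
#' cellular autofluorescence with a large width plus a flat baseline.
#'
#' @return list of three \linkS4class{SpectrumModel}: NucBlue, Cal520, AF.
#' @export
exampleModels <- function() {
  list(
    spectrumModel("NucBlue", peakNm = 360, widthNm = 25, baseline = 0.02),
    spectrumModel("Cal520", peakNm = 495, widthNm = 40, baseline = 0.01),
    spectrumModel("AF", peakNm = 420, widthNm = 120, baseline = 0.35)
  )
}

#' Two-component autofluorescence sub-models
#'
#' Cellular autofluorescence is a mixture of fluorophores rather than a
#' single species; over a 360-480 nm excitation scan the dominant
#' contributors are a blue-excited NAD(P)H-like component and a
#' green-excited flavin-like component. Scenes that mix these two
#' sub-components in cell-dependent ratios show realistic pixel-to-pixel
#' autofluorescence spectral variability even though each sub-component's
#' spectrum is fixed — the analysis library then carries only the single
#' pooled AF reference measured from an unlabeled control, exactly as an
#' experiment would.
#'
#' @return list of two \linkS4class{SpectrumModel}: AFb (NAD(P)H-like,
#'   360-weighted) and AFg (flavin-like, 455-weighted).
#' @seealso \code{\link{controlScene}}, \code{\link{exampleScene}}
#' @export
afSubModels <- function() {
  list(
    spectrumModel("AFb", peakNm = 365, widthNm = 60, baseline = 0.15),
    spectrumModel("AFg", peakNm = 455, widthNm = 60, baseline = 0.15)
  )
}

# Four-model set used by scenes with heterogeneous autofluorescence.
heteroModels <- function()
  c(exampleModels()[1:2], afSubModels())

heteroRoles <- c(nuc = "NucBlue", ca = "Cal520", af = "AFb",
                 af2 = "AFg")

#' Ready-made synthetic scenes
#'
#' Three presets covering the package's standard study conditions:
#' \describe{
#'   \item{\code{"calcium"}}{A dual-labeled time-lapse acquisition:
#'     25 excitation bands (360-480 nm in 5 nm steps), one frame every 30 s
#'     for 15 min (31 frames), 96 x 96 pixels, five cells with
#'     agonist-triggered Ca2+ transients starting at 300 s (after 5 min of
#'     baseline); one cell oscillates, one is quiescent. Poisson shot noise
#'     with gain 0.18 intensity units/count, putting the peak-intensity
#'     pixels near SNR 20.}
#'   \item{\code{"background"}}{The sensitivity-analysis background: a
#'     near-confluent field carrying every spectral component except the
#'     target — nuclear label and cellular autofluorescence in nine cells,
#'     plus a diffuse background autofluorescence floor — single frame,
#'     96 x 96 pixels, Poisson gain 0.5. Injecting the Ca2+ label into an
#'     ROI of this image creates a known simulated ground truth; the
#'     pixel-to-pixel variation in nuclear-to-autofluorescence ratio gives
#'     the image the spectral-shape diversity a labeled culture shows.}
#'   \item{\code{"tiny"}}{A 5-band, 4-frame, 16 x 16 scene with one cell,
#'     for fast smoke tests.}
#' }
#'
#' @param preset one of \code{"calcium"}, \code{"background"},
#'   \code{"tiny"}.
#' @param noise override the preset's noise model (\code{"none"},
#'   \code{"gaussian"}, \code{"poisson"}); default keeps the preset's.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticScene}.
#' @examples
#' exampleScene("tiny", seed = 2)
#' @export
exampleScene <- function(preset = c("calcium", "background", "tiny"),
                         noise = NULL, seed = 1L) {
  preset <- match.arg(preset)
  models <- exampleModels()
  wl <- seq(360, 480, by = 5)
  scene <- switch(preset,
    calcium = syntheticScene(
      wavelengths = wl, frameInterval = 30, nFrames = 31L,
      imageShape = c(96L, 96L),
      cells = list(
        cellSpec(c(26, 26), c(15, 11), c(6, 4), caBaseline = 8,
                 caTransient = c(300, 25, 150, NA), nucLevel = 60,
                 afLevel = 15),
        cellSpec(c(26, 72), c(12, 14), c(4, 5), caBaseline = 6,
                 caTransient = c(300, 30, 120, 120), nucLevel = 50,
                 afLevel = 18),
        cellSpec(c(70, 24), c(13, 12), c(5, 4), caBaseline = 10,
                 caTransient = c(300, 20, 180, NA), nucLevel = 70,
                 afLevel = 12),
        cellSpec(c(72, 70), c(14, 13), c(5, 5), caBaseline = 7,
                 caTransient = c(0, 0, 1, NA), nucLevel = 55,
                 afLevel = 20),
        cellSpec(c(48, 48), c(10, 10), c(4, 4), caBaseline = 9,
                 caTransient = c(300, 35, 150, NA), nucLevel = 65,
                 afLevel = 16)
      ),
      endmemberModels = models,
      noiseModel = "poisson", noiseScale = 0.18, seed = seed),
    background = syntheticScene(
      wavelengths = wl, frameInterval = 30, nFrames = 1L,
      imageShape = c(96L, 96L),
      cells = list(
        # af:af2 splits vary cell to cell (flavin-rich to NADH-rich),
        # emulating heterogeneous cellular autofluorescence
        cellSpec(c(18, 16), c(10, 15), c(4.5, 6.8), nucLevel = 60,
                 afLevel = 4, af2Level = 10),
        cellSpec(c(42, 16), c(11, 15), c(5.0, 6.8), nucLevel = 52,
                 afLevel = 10, af2Level = 5),
        cellSpec(c(76, 11), c(13, 10), c(5.9, 4.5), nucLevel = 57,
                 afLevel = 9, af2Level = 10),
        cellSpec(c(16, 47), c(15, 17), c(6.8, 7.7), nucLevel = 53,
                 afLevel = 6, af2Level = 9),
        cellSpec(c(47, 44), c(15, 12), c(6.8, 5.5), nucLevel = 46,
                 afLevel = 13, af2Level = 4),
        cellSpec(c(79, 44), c(15, 16), c(6.8, 7.3), nucLevel = 61,
                 afLevel = 9, af2Level = 7),
        cellSpec(c(14, 83), c(13, 13), c(5.9, 5.9), nucLevel = 40,
                 afLevel = 6, af2Level = 11),
        cellSpec(c(47, 83), c(16, 13), c(7.3, 5.9), nucLevel = 59,
                 afLevel = 10, af2Level = 6),
        cellSpec(c(73, 79), c(16, 17), c(7.3, 7.7), nucLevel = 61,
                 afLevel = 10, af2Level = 10)
      ),
      endmemberModels = heteroModels(), roles = heteroRoles,
      bgLevel = 3, noiseModel = "poisson", noiseScale = 0.5,
      seed = seed),
    tiny = syntheticScene(
      wavelengths = seq(400, 480, by = 20), frameInterval = 30,
      nFrames = 4L, imageShape = c(16L, 16L),
      cells = list(
        cellSpec(c(8, 8), c(5, 5), c(2, 2), caBaseline = 5,
                 caTransient = c(30, 15, 60, NA), nucLevel = 30,
                 afLevel = 10)
      ),
      endmemberModels = models, noiseModel = "none", noiseScale = 0,
      seed = seed)
  )
  if (!is.null(noise)) {
    noise <- match.arg(noise, c("none", "gaussian", "poisson"))
    if (noise == "none") scene@noiseScale <- 0
    else if (scene@noiseScale == 0) scene@noiseScale <- 0.18
    scene@noiseModel <- noise
  }
  validObject(scene)
  scene
}

#' Single-label control scenes
#'
#' Renders the three single-label control acquisitions from which reference
#' spectra are conventionally measured: \code{"nuc"} (nuclear label plus
#' residual autofluorescence), \code{"ca"} (Ca2+ label plus residual
#' autofluorescence) and \code{"af"} (unlabeled cells). Single frame,
#' 96 x 96 pixels, Poisson gain 0.5, diffuse background floor 3.
#'
#' @param label one of \code{"nuc"}, \code{"ca"}, \code{"af"}.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticScene}.
#' @seealso \code{\link{measuredLibrary}}
#' @export
controlScene <- function(label = c("nuc", "ca", "af"), seed = 1L) {
  label <- match.arg(label)
  cells <- switch(label,
    nuc = list(
      cellSpec(c(30, 30), c(16, 14), c(7, 6), nucLevel = 80,
               afLevel = 4, af2Level = 4),
      cellSpec(c(40, 70), c(14, 16), c(6, 7), nucLevel = 70,
               afLevel = 6, af2Level = 4),
      cellSpec(c(70, 40), c(15, 15), c(6, 6), nucLevel = 90,
               afLevel = 3, af2Level = 5)),
    ca = list(
      cellSpec(c(30, 30), c(16, 14), c(7, 6), caBaseline = 50,
               afLevel = 2, af2Level = 3),
      cellSpec(c(40, 70), c(14, 16), c(6, 7), caBaseline = 40,
               afLevel = 3, af2Level = 3),
      cellSpec(c(70, 40), c(15, 15), c(6, 6), caBaseline = 60,
               afLevel = 3, af2Level = 2)),
    af = list(
      cellSpec(c(30, 30), c(16, 14), c(7, 6), afLevel = 9,
               af2Level = 11),
      cellSpec(c(40, 70), c(14, 16), c(6, 7), afLevel = 10,
               af2Level = 6),
      cellSpec(c(70, 40), c(15, 15), c(6, 6), afLevel = 12,
               af2Level = 10)))
  syntheticScene(seq(360, 480, by = 5), 30, 1L, c(96L, 96L),
                 cells = cells, endmemberModels = heteroModels(),
                 roles = heteroRoles, bgLevel = 3,
                 noiseModel = "poisson", noiseScale = 0.5, seed = seed)
}

#' Bright-signal ROI for reference extraction
#'
#' Selects the pixels whose band-summed intensity exceeds a fraction of the
#' image maximum — the programmatic counterpart of drawing a region over an
#' area of intense (but not oversaturated; saturation is handled separately
#' by \code{\link{extractReference}}) signal.
#'
#' @param stack a \linkS4class{SpectralStack}.
#' @param frac fraction of the maximum summed intensity (default 0.5).
#' @return logical matrix.
#' @export
brightROI <- function(stack, frac = 0.5) {
  s <- apply(stack@data, c(2L, 3L), sum)
  s > frac * max(s)
}

#' Build a spectral library the way an experiment would
#'
#' Renders the three single-label control scenes, selects a bright ROI in
#' each, extracts the pixel-averaged peak-normalized reference spectrum,
#' and assembles the library. Unlike the generative library of
#' \code{\link{makeLibrary}}, these references carry measurement noise and
#' slight cross-contamination (e.g. residual autofluorescence under the
#' label signal) — the realistic input condition for the detectors and the
#' sensitivity analysis.
#'
#' @param seed integer seed for the control renders.
#' @return a \linkS4class{SpectralLibrary} with endmembers NucBlue, Cal520,
#'   AF.
#' @export
measuredLibrary <- function(seed = 1L) {
  refs <- lapply(c(nuc = "nuc", ca = "ca", af = "af"), function(lb) {
    st <- renderScene(controlScene(lb, seed = seed))$stacks[[1L]]
    extractReference(st, brightROI(st))
  })
  assembleLibrary(list(NucBlue = refs$nuc, Cal520 = refs$ca,
                       AF = refs$af),
                  seq(360, 480, by = 5))
}

#' Injection ROI for the sensitivity analysis presets
#'
#' Returns the body mask of one cell of a rendered scene, the conventional
#' injection region for the theoretical sensitivity analysis (a region that
#' contains background spectral components but no target endmember).
#'
#' @param truth a \linkS4class{GroundTruth} from \code{\link{renderScene}}.
#' @param cell which cell's body mask to use.
#' @return logical matrix.
#' @export
exampleROI <- function(truth, cell = 1L) {
  stopIfNot(length(truth@masks) >= cell, "exampleROI: no such cell")
  truth@masks[[cell]]
}
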