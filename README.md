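# hsiDetect

Spectral detection and kinetic trace extraction for **excitation-scanning
hyperspectral fluorescence microscopy**.

Excitation-scanning HSI tunes a narrow excitation band (here 360–480 nm
in 5 nm steps) while collecting broadband emission, so each pixel samples
the *excitation* spectra of the fluorophores beneath it — with enough
photon throughput for time-lapse imaging of live cells. The hard part is
analysis: a weak, dynamic label signal (e.g. a Ca²⁺ indicator in airway
smooth muscle cells) must be separated from a nuclear label and from
broad, spatially variable cellular autofluorescence occupying the same
wavelength range.

hsiDetect is written for microscopists and image analysts who need that
separation to be quantitative. Every pixel is modeled as a linear
mixture of peak-normalized endmember spectra,
`x = Σ aᵢ rᵢ + w, aᵢ ≥ 0`, and the package provides:

* **Preprocessing** — background subtraction and flat spectral-response
  correction `cc = Φ⁻¹ / max(Φ⁻¹)` from a measured illumination-power
  table; multi-page TIFF I/O with wavelength sidecars.
* **Library construction** — saturation-aware, ROI-averaged,
  peak-normalized reference spectra from single-label control images.
* **Four pixel-wise detectors** —
  non-negatively constrained linear unmixing (**LU**, batched
  Lawson–Hanson NNLS with per-pixel RMS residuals), spectral angle
  mapper (**SAM**, `θ = arccos(r·x / ‖r‖‖x‖)`), constrained energy
  minimization (**CEM**, `L = R⁻¹r (rᵀR⁻¹r)⁻¹` with unity gain on the
  target), and matched filter (**MF**, rejection operator `P = I − UU#`,
  `q = rᵀP`, `a = q·x`).
* **Theoretical sensitivity analysis** — inject `x′ = x + a·r` into an
  ROI of a target-free image and produce the sensitivity curve (TSC),
  thresholded positive-pixel curve (TPPC), ROC curve with AUC, and a
  minimum detectable limit (MDL) for any detector.
* **Pixel filtering and kinetics** — TSA- or Otsu-derived thresholds,
  binary pass masks, and whole-field / single-cell time traces that
  average only pixels above the detection limit.
* **A synthetic scene generator** — cell-shaped abundance maps,
  agonist-triggered Ca²⁺ transients, two-component heterogeneous
  autofluorescence, Poisson shot noise, and exact ground truth, so the
  entire pipeline is testable without any external data.

## A worked example

Run the sensitivity analysis for the matched filter on the default
synthetic background field, using a spectral library measured from
single-label controls exactly as an experiment would:

```r
library(hsiDetect)

bg  <- renderScene(exampleScene("background", seed = 1))
lib <- measuredLibrary(seed = 1)
lib
#> SpectralLibrary: 3 endmembers x 25 bands (360-480 nm)
#>   endmembers: NucBlue, Cal520, AF

cfg <- tsaConfig(exampleROI(bg$truth), "Cal520", "MF")
res <- runTSA(bg$stacks[[1]], cfg, lib)
res
#> TSAResult [MF] target 'Cal520'
#>   TSC: 31 injection levels, slope 1.711, R^2 1
#>   ROC: AUC 0.9943; MDL 15
```

The matched filter responds linearly to injected Ca²⁺-label signal
(slope 1.711 in map units per unit of injected abundance, R² = 1),
separates target from background almost ideally at injection level 5
(AUC 0.994), and its background outputs stay below 15 map units — the
minimum detectable limit used next as a pixel filter.

```r
cal   <- renderScene(exampleScene("calcium", seed = 1))
op    <- mfBuild(cal$truth@library, "Cal520")
maps  <- lapply(cal$stacks, function(s) mfApply(op, s))
times <- vapply(cal$stacks, function(s) s@timeS, 0)
tr <- extractTrace(maps, matrix(TRUE, 96, 96),
                   pixelFilter(res@mdl, "tsa"), timesS = times)
round(traceToFrame(tr)[9:13, ], 3)
#>    time_s   mean n_pixels
#> 9     240 16.782      499
#> 10    270 16.946      505
#> 11    300 47.522     1868
#> 12    330 46.201     1870
#> 13    360 35.806     1877
```

The filtered whole-field trace jumps at t = 300 s — the programmed
agonist addition after 5 min of baseline — and the passing-pixel count
rises from ~500 (only the brightest resting pixels clear the limit) to
~1870 as cells respond; averaging only those pixels keeps the response
amplitude from being diluted by background.

A thin command-line tool (`inst/scripts/hsidetect`) wires the same
functions into `simulate`, `correct`, `library`, `unmix`, `tsa` and
`trace` subcommands, each writing a replayable `manifest.json`.

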