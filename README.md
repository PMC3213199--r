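# pc4dflow

Quantification and quality assessment of time-resolved three-dimensional
velocity-encoded (4D flow) phase-contrast cardiovascular MR.

4D flow acquisitions record a magnitude image and three velocity components
per voxel per cardiac phase, with velocity encoded in the signal phase
(`v = (phase/pi) * VENC`). Turning that into clinical numbers — vessel flow
curves, stroke volume, QP/QS, intracardiac flow visualisation — requires a
chain of steps, each of which can bias the result: eddy-current background
phase, velocity aliasing beyond the VENC, resampling onto oblique vessel
planes, contour-based flow integration, and pathline tracing through the
measured field. This package implements that chain and, because in vivo
data has no accessible ground truth, pairs it with a synthetic pulsatile
tube-flow phantom in which every quantity is known in closed form, so each
link can be validated mechanistically.

For whom: developers and users of 4D-flow analysis software who need a
tested, scriptable reference chain, and methodologists studying how
acquisition effects (noise, aliasing, temporal blurring from k-t
undersampling, prospective-gating truncation) propagate into flow
quantities.

## What is implemented

* **Phantom** — rigid tube with pulsatile Poiseuille flow,
  `v(r,t) = v_max(t)(1 - (r/R)^2)`, `v_max(t) = 2Q(t)/(pi R^2)`, waveform a
  truncated Fourier series (default: aortic-like, peak 400 ml/s, SV 95 ml,
  1000 ms cycle), sampled at 3 mm / 50 ms with analytic ground truth;
  artifact operators for velocity noise, phase wrap, Hann temporal
  blurring, and prospective truncation. (`phantomSpec()`,
  `generatePhantom()`, `applyTemporalBlur()`,
  `applyProspectiveTruncation()`)
* **Preprocessing** — static-tissue detection, first-order
  (`c0 + c1 x + c2 y + c3 z`) background-phase fit per velocity component
  with robust trimming, exact invertible correction, and temporal velocity
  unwrapping anchored at the minimum-speed frame. (`detectStaticTissue()`,
  `fitBackground()`, `correctBackground()`, `unwrapVelocity()`)
* **Reformatting** — trilinear resampling of the 4D dataset onto arbitrary
  oblique planes, `v_through = v . n`, with invalid-pixel tracking.
  (`planeDefinition()`, `reformatPlane()`)
* **Flow quantification** — threshold-grown vessel contours, flow curves by
  pixel-centre containment sums, stroke volume by cyclic (or
  truncation-aware) trapezoidal integration, SNR with the
  Rayleigh-background 0.655 correction, QP/QS. (`segmentVessel()`,
  `computeFlowCurve()`, `computeSNR()`, `computeQpQs()`)
* **Pathlines** — fixed-step RK4 particle tracing with timed emitters
  (default release every 10 ms), blood-pool containment statistics and the
  0-3 quality grading with mean score. (`tracePathlines()`,
  `gradeContainment()`)
* **Agreement statistics** — OLS regression, Bland-Altman percent bias
  (reference-denominator, with the pair-mean convention alongside), and an
  exact paired Wilcoxon signed-rank test (mid-ranks, zeros dropped, exact
  null for n <= 25). (`agreement()`, `wilcoxonSignedRank()`,
  `percentBias()`)
* **Pipeline** — `runPipeline()` chains phantom → preprocess → reformat →
  flow → trace (→ compare), writing every intermediate plus the effective
  configuration; identical config + seed gives byte-identical outputs. A
  command-line front end (`inst/exec/pc4dflow`) exposes each stage as a
  subcommand.

All on-disk formats are standard: NIfTI volumes (float64), JSON metadata,
CSV flow curves / contours / pathlines.

## Worked example

```r
library(pc4dflow)

## default phantom: R = 12 mm tube, 32^3 grid at 3 mm, 20 frames / 1000 ms
p <- generatePhantom(phantomSpec())
strokeVolume(p$truth)
#> [1] 95

## oblique plane ~15 degrees off the vessel axis, 1.5 mm pixels
plane <- planeDefinition(c(0, 0, 0), normal = c(0, sin(0.26), cos(0.26)),
                         pixelSize = 1.5, extent = c(40L, 40L))
series <- reformatPlane(p$field, plane)
contour <- segmentVessel(series, seedPointMm = c(0, 0))
contourArea(contour)        # ellipse through the tilted tube, mm^2
#> [1] 468

fc <- computeFlowCurve(series, contour)
fc
#> FlowCurve: 20 frames; SV 93.27 ml; peak 392.7 ml/s; coverage full
100 * (strokeVolume(fc) - strokeVolume(p$truth)) / strokeVolume(p$truth)
#> [1] -1.817028
```

The -1.8 % stroke-volume error is the discretisation floor of 3 mm voxels
on a 24 mm vessel (trilinear sampling of the parabolic profile plus the
threshold contour), and shrinks quadratically with voxel size. Adding
noise at SNR 15, injecting a background offset and correcting it, or
halving the VENC and unwrapping all return to within a few percent of this
floor — see the vignette in `vignettes/flow-phantom-validation.Rmd` for the
full story and for every numerical convention (truncated-cycle
integration, unwrap anchoring, grading thresholds, Wilcoxon tie handling).

The end-to-end chain with all intermediates on disk:

```r
res <- runPipeline(list(out_dir = "run1", seed = 1L))
res$svReport$sv_error_percent   # axis-normal plane, after preprocessing
#> [1] -2.665251
```

or from a shell: `inst/exec/pc4dflow run --out run1 --seed 1`.

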