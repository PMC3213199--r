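#' @include AllClasses.R utils.R
NULL

## Default aortic-like waveform: mean 95 ml/s plus four harmonics peaking at
## t0 = 150 ms of a 1000 ms cycle -> peak 400 ml/s, SV 95 ml, minimum flow
## +4.8 ml/s (nonnegative). Phases are -k w t0 so harmonic k is
## amp_k * cos(k w (t - t0)).
.defaultHarmonics <- function(cycleMs = 1000, t0 = 150) {
  amps <- c(150, 95, 45, 15)
  w <- 2 * pi / cycleMs
  cbind(amplitude = amps, phase = -(seq_along(amps)) * w * t0)
}

#' Construct a phantom specification
#'
#' Builds a validated [PhantomSpec-class]. Defaults emulate a typical
#' whole-heart 4D phase-contrast acquisition (3 mm isotropic voxels, 20
#' frames over a 1000 ms cycle, VENC 2000 mm/s) around an aorta-sized tube
#' (radius 12 mm) carrying a pulsatile waveform with systolic peak 400 ml/s
#' and stroke volume 95 ml.
#'
#' @param tubeAxis unit vector along the tube (normalised internally).
#' @param tubeCenter point on the axis, mm; default the grid centre.
#' @param radius tube radius, mm.
#' @param gridShape voxels per axis.
#' @param voxelSize mm, scalar or length 3.
#' @param cycleMs cardiac cycle length, ms.
#' @param nFrames number of frames (equally spaced from 0).
#' @param meanFlow mean flow, ml/s.
#' @param harmonics k x 2 matrix (amplitude ml/s, phase rad); see
#'   [PhantomSpec-class].
#' @param venc velocity-encoding limit, mm/s.
#' @param noiseSd per-component velocity noise SD, mm/s.
#' @param backgroundCoeffs length-4 `(a0, a1, a2, a3)` first-order background
#'   offset applied along the tube axis, mm/s and mm/s per mm.
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noiseSd = 0)
#' spec
#' @export
phantomSpec <- function(tubeAxis = c(0, 0, 1), tubeCenter = c(0, 0, 0),
                        radius = 12, gridShape = c(32L, 32L, 32L),
                        voxelSize = 3, cycleMs = 1000, nFrames = 20L,
                        meanFlow = 95, harmonics = .defaultHarmonics(cycleMs),
                        venc = 2000, noiseSd = 0,
                        backgroundCoeffs = c(0, 0, 0, 0), seed = 1L) {
  tubeAxis <- tubeAxis / sqrt(sum(tubeAxis^2))
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (nFrames < 2L) stop("timing error: nFrames must be >= 2")
  new("PhantomSpec",
      tubeAxis = as.numeric(tubeAxis), tubeCenter = as.numeric(tubeCenter),
      radius = as.numeric(radius), gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), cycleMs = as.numeric(cycleMs),
      nFrames = as.integer(nFrames), meanFlow = as.numeric(meanFlow),
      harmonics = harmonics, venc = as.numeric(venc),
      noiseSd = as.numeric(noiseSd),
      backgroundCoeffs = as.numeric(backgroundCoeffs), seed = as.integer(seed))
}

#' Evaluate a phantom's analytic flow waveform
#'
#' @param spec a [PhantomSpec-class].
#' @param timesMs times at which to evaluate, ms.
#' @return Flow in ml/s at each time.
#' @export
phantomFlowWaveform <- function(spec, timesMs) {
  w <- 2 * pi / spec@cycleMs
  q <- rep(spec@meanFlow, length(timesMs))
  for (k in seq_len(nrow(spec@harmonics)))
    q <- q + spec@harmonics[k, 1] * cos(k * w * timesMs + spec@harmonics[k, 2])
  q
}

#' Construct a VelocityField4D from arrays
#'
#' Low-level constructor used by the phantom generator, the readers, and by
#' tests that build analytic fields (e.g. rigid rotations) directly.
#'
#' @param velocity `nx x ny x nz x nt x 3` array, mm/s.
#' @param magnitude `nx x ny x nz x nt` array; default all ones.
#' @param voxelSize mm, scalar or length 3.
#' @param origin world position of the first voxel centre, mm.
#' @param triggerTimes ms, strictly increasing, `< cycleMs`.
#' @param cycleMs cycle length, ms.
#' @param venc mm/s.
#' @param coverage `"full"` or `"truncated"`.
#' @param coveredMs covered cycle portion, ms (default `cycleMs`).
#' @param stage `"wrapped"` or `"unwrapped"`.
#' @return A [VelocityField4D-class].
#' @export
velocityField4D <- function(velocity, magnitude = NULL, voxelSize, origin,
                            triggerTimes, cycleMs, venc,
                            coverage = "full", coveredMs = cycleMs,
                            stage = "wrapped") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(magnitude))
    magnitude <- array(1, dim = dim(velocity)[1:4])
  new("VelocityField4D", velocity = velocity, magnitude = magnitude,
      voxelSize = as.numeric(voxelSize), origin = as.numeric(origin),
      triggerTimes = as.numeric(triggerTimes), cycleMs = as.numeric(cycleMs),
      coveredMs = as.numeric(coveredMs), venc = as.numeric(venc),
      coverage = coverage, stage = stage)
}

## World coordinates of every voxel centre, as three nx x ny x nz arrays.
.voxelCoords <- function(gridShape, voxelSize, origin) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  xs <- origin[1] + (seq_len(nx) - 1) * voxelSize[1]
  ys <- origin[2] + (seq_len(ny) - 1) * voxelSize[2]
  zs <- origin[3] + (seq_len(nz) - 1) * voxelSize[3]
  list(
    x = array(rep(xs, times = ny * nz), dim = gridShape),
    y = array(rep(rep(ys, each = nx), times = nz), dim = gridShape),
    z = array(rep(zs, each = nx * ny), dim = gridShape)
  )
}

#' Generate a synthetic 4D phase-contrast dataset with ground truth
#'
#' Realises the phantom described by `spec`: an axial parabolic (Poiseuille)
#' velocity profile `v(r, t) = v_max(t) (1 - (r/R)^2)` with
#' `v_max(t) = 2 Q(t) / (pi R^2)` inside the tube and zero mean velocity in
#' static tissue; then, in acquisition order, the first-order background
#' offset is added along the tube axis, Gaussian velocity noise is added to
#' every component, and each component is phase-wrapped into `(-venc, venc]`.
#' Voxel velocities are the analytic profile at the voxel centre; mask
#' membership is by centre-inside-radius.
#'
#' The magnitude image models a body ellipsoid of signal 100 embedded in air:
#' the complex-signal noise SD implied by `noiseSd` (via the phase-contrast
#' relation `sigma_v = sqrt(2) venc sigma_m / (pi A)`, A = 100) gives
#' Rician-distributed magnitude inside the body and Rayleigh background
#' outside, so [computeSNR()]'s Rayleigh-corrected formula applies.
#'
#' Identical `spec` (including its `seed`) reproduces the dataset exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `field` ([VelocityField4D-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' p <- generatePhantom(phantomSpec())
#' strokeVolume(p$truth)
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  vs <- spec@voxelSize
  nt <- spec@nFrames
  origin <- -(gs - 1) / 2 * vs   # grid centred on the world origin
  tt <- (seq_len(nt) - 1) * spec@cycleMs / nt

  co <- .voxelCoords(gs, vs, origin)
  dx <- co$x - spec@tubeCenter[1]
  dy <- co$y - spec@tubeCenter[2]
  dz <- co$z - spec@tubeCenter[3]
  a <- spec@tubeAxis
  axial <- dx * a[1] + dy * a[2] + dz * a[3]
  r2 <- pmax(dx^2 + dy^2 + dz^2 - axial^2, 0)
  inTube <- r2 <= spec@radius^2

  if (!any(inTube))
    stop("geometry error: grid too small to contain the tube")
  ## tube must not leak through faces that are not (close to) axis-normal
  faceNormals <- diag(3)
  for (k in 1:3) {
    if (abs(sum(faceNormals[k, ] * a)) > 0.99) next
    idx <- switch(k,
      inTube[c(1, gs[1]), , ],
      inTube[, c(1, gs[2]), ],
      inTube[, , c(1, gs[3])])
    if (any(idx))
      stop("geometry error: grid too small to contain the tube")
  }

  qml <- phantomFlowWaveform(spec, tt)
  vmax <- 2 * qml * 1000 / (pi * spec@radius^2)   # ml/s -> mm^3/s
  profile <- (1 - r2 / spec@radius^2) * inTube

  ## body ellipsoid (signal-bearing tissue) and static tissue
  half <- (gs - 1) / 2 * vs
  cx <- (co$x - (origin[1] + half[1])) / (0.85 * half[1])
  cy <- (co$y - (origin[2] + half[2])) / (0.85 * half[2])
  cz <- (co$z - (origin[3] + half[3])) / (0.85 * half[3])
  inBody <- (cx^2 + cy^2 + cz^2) <= 1 | inTube
  staticMask <- inBody & !inTube

  bg <- spec@backgroundCoeffs[1] + spec@backgroundCoeffs[2] * co$x +
    spec@backgroundCoeffs[3] * co$y + spec@backgroundCoeffs[4] * co$z

  nvox <- prod(gs)
  vel <- array(0, dim = c(gs, nt, 3L))
  A <- 100
  sigM <- if (spec@noiseSd > 0) pi * A * spec@noiseSd / (sqrt(2) * spec@venc) else 0
  mag <- array(0, dim = c(gs, nt))

  .withSeed(spec@seed, {
    for (f in seq_len(nt)) {
      vf <- vmax[f] * profile
      for (comp in 1:3) {
        plane <- a[comp] * vf + a[comp] * bg
        if (spec@noiseSd > 0)
          plane <- plane + stats::rnorm(nvox, sd = spec@noiseSd)
        vel[, , , f, comp] <- wrapToVenc(plane, spec@venc)
      }
      sig <- A * inBody
      if (sigM > 0) {
        mag[, , , f] <- sqrt((sig + stats::rnorm(nvox, sd = sigM))^2 +
                             stats::rnorm(nvox, sd = sigM)^2)
      } else {
        mag[, , , f] <- sig
      }
    }
  })

  field <- velocityField4D(vel, mag, voxelSize = vs, origin = origin,
                           triggerTimes = tt, cycleMs = spec@cycleMs,
                           venc = spec@venc)
  sv <- .cyclicTrapz(tt, qml, spec@cycleMs)
  truth <- new("GroundTruth", timeMs = tt, flowMlS = qml,
               strokeVolumeMl = sv, peakFlowMlS = max(qml),
               bloodPoolMask = inTube, staticMask = staticMask,
               cycleMs = spec@cycleMs)
  list(field = field, truth = truth)
}

#' Temporal low-pass blurring of a velocity field
#'
#' Emulates the temporal blurring that k-t undersampled reconstructions
#' impose on velocity waveforms: every voxel's velocity (and magnitude) time
#' series is circularly convolved with a normalised Hann kernel. The kernel
#' integrates to one, so each voxel's time average — and hence the stroke
#' volume of any full-coverage flow curve — is preserved, while waveform
#' peaks are attenuated.
#'
#' @param field a [VelocityField4D-class] with full cycle coverage.
#' @param kernelWidthFrames kernel width in frames (>= 1); rounded to the
#'   nearest odd number of taps. Width 1 is the identity.
#' @return The blurred [VelocityField4D-class].
#' @export
applyTemporalBlur <- function(field, kernelWidthFrames) {
  stopifnot(is(field, "VelocityField4D"))
  if (kernelWidthFrames < 1)
    stop("parameter error: kernelWidthFrames must be >= 1")
  nt <- nFrames(field)
  L <- 2L * floor(kernelWidthFrames / 2) + 1L
  if (L > nt)
    stop("parameter error: kernel wider than the cardiac cycle")
  if (L == 1L) return(field)
  h <- temporalBlurKernel(kernelWidthFrames)
  half <- (L - 1L) / 2L
  offs <- -half:half
  vel <- array(0, dim = dim(field@velocity))
  mag <- array(0, dim = dim(field@magnitude))
  for (k in seq_along(offs)) {
    src <- ((seq_len(nt) - 1 + offs[k]) %% nt) + 1
    vel <- vel + h[k] * field@velocity[, , , src, , drop = FALSE]
    mag <- mag + h[k] * field@magnitude[, , , src, drop = FALSE]
  }
  out <- field
  out@velocity <- vel
  out@magnitude <- mag
  out
}

#' Hann kernel used by [applyTemporalBlur()]
#'
#' @param kernelWidthFrames width in frames; rounded to an odd tap count.
#' @return Normalised kernel weights (sum 1), centre tap in the middle.
#' @export
temporalBlurKernel <- function(kernelWidthFrames) {
  L <- 2L * floor(kernelWidthFrames / 2) + 1L
  m <- seq_len(L)
  h <- sin(pi * m / (L + 1))^2
  h / sum(h)
}

#' Prospective-gating truncation of the cardiac cycle
#'
#' Emulates prospective ECG triggering, which stops acquiring before the
#' R-wave and so misses late diastole: frames with trigger time at or beyond
#' `retainedFraction * cycleMs` are removed and the dataset is flagged
#' `truncated` with `coveredMs = retainedFraction * cycleMs`, so downstream
#' stroke-volume integration is restricted to the covered support.
#'
#' @param field a [VelocityField4D-class].
#' @param retainedFraction fraction of the cycle retained, in (0, 1];
#'   1 returns the input unchanged.
#' @return A [VelocityField4D-class] (possibly truncated).
#' @export
applyProspectiveTruncation <- function(field, retainedFraction) {
  stopifnot(is(field, "VelocityField4D"))
  if (retainedFraction <= 0 || retainedFraction > 1)
    stop("parameter error: retainedFraction must be in (0, 1]")
  if (retainedFraction == 1) return(field)
  keep <- field@triggerTimes < retainedFraction * field@cycleMs
  if (sum(keep) < 2L)
    stop("timing error: truncation leaves fewer than 2 frames")
  out <- field
  out@velocity <- field@velocity[, , , keep, , drop = FALSE]
  out@magnitude <- field@magnitude[, , , keep, drop = FALSE]
  out@triggerTimes <- field@triggerTimes[keep]
  out@coverage <- "truncated"
  out@coveredMs <- retainedFraction * field@cycleMs
  out
}
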