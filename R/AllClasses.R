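#' @import methods
NULL

#' Time-resolved 3D phase-contrast velocity dataset
#'
#' Central container of the package: a three-component velocity field plus a
#' magnitude image on a regular voxel grid, sampled at a set of cardiac
#' trigger times. Velocities are stored in mm/s (phase data are converted via
#' v = (phase/pi) * VENC at ingest). World coordinates are right-handed
#' millimetres; the voxel with (0-based) index (i, j, k) has its centre at
#' `origin + c(i, j, k) * voxelSize`. Time is milliseconds from the R-wave.
#'
#' @slot velocity 5-D numeric array `nx x ny x nz x nt x 3` (mm/s), component
#'   order x, y, z.
#' @slot magnitude 4-D numeric array `nx x ny x nz x nt` (arbitrary units).
#' @slot voxelSize length-3 numeric, mm per axis.
#' @slot origin length-3 numeric, mm; world position of the first voxel centre.
#' @slot triggerTimes numeric, ms; strictly increasing, all `< cycleMs`.
#' @slot cycleMs scalar, cardiac cycle length in ms.
#' @slot coveredMs scalar, portion of the cycle covered by the acquisition
#'   (equals `cycleMs` for retrospectively gated full-cycle data).
#' @slot venc scalar velocity-encoding limit, mm/s; stored velocities satisfy
#'   |v| <= venc while `stage == "wrapped"`.
#' @slot coverage `"full"` or `"truncated"` (prospective gating misses late
#'   diastole).
#' @slot stage `"wrapped"` (as acquired, aliased beyond VENC) or `"unwrapped"`.
#'
#' @seealso [velocityField4D()], [generatePhantom()], [reformatPlane()]
#' @export
setClass("VelocityField4D",
  slots = c(
    velocity = "array",
    magnitude = "array",
    voxelSize = "numeric",
    origin = "numeric",
    triggerTimes = "numeric",
    cycleMs = "numeric",
    coveredMs = "numeric",
    venc = "numeric",
    coverage = "character",
    stage = "character"
  )
)

setValidity("VelocityField4D", function(object) {
  dv <- dim(object@velocity)
  dm <- dim(object@magnitude)
  if (length(dv) != 5L || dv[5] != 3L)
    return("velocity must be an nx x ny x nz x nt x 3 array")
  if (length(dm) != 4L || !all(dm == dv[1:4]))
    return("magnitude dimensions must match velocity spatial/temporal dimensions")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  nt <- dv[4]
  tt <- object@triggerTimes
  if (length(tt) != nt)
    return("length(triggerTimes) must equal the number of frames")
  if (nt < 2L)
    return("at least 2 frames are required")
  if (any(diff(tt) <= 0))
    return("triggerTimes must be strictly increasing")
  if (any(tt >= object@cycleMs))
    return("all triggerTimes must be < cycleMs")
  if (length(object@venc) != 1L || !is.finite(object@venc) || object@venc <= 0)
    return("venc must be a positive scalar (mm/s)")
  if (!object@coverage %in% c("full", "truncated"))
    return("coverage must be 'full' or 'truncated'")
  if (!object@stage %in% c("wrapped", "unwrapped"))
    return("stage must be 'wrapped' or 'unwrapped'")
  if (!is.finite(object@coveredMs) || object@coveredMs <= 0 ||
      object@coveredMs > object@cycleMs)
    return("coveredMs must lie in (0, cycleMs]")
  TRUE
})

#' Synthetic pulsatile tube-flow phantom specification
#'
#' Defines a straight rigid tube carrying laminar pulsatile (Poiseuille)
#' flow inside a body "ellipsoid" of static tissue, together with the
#' acquisition parameters used to encode it: VENC, velocity noise, a
#' first-order (linear-in-space) background phase offset, and the voxel /
#' temporal sampling grid. The default geometry and timing emulate a typical
#' whole-heart 4D acquisition: 3 mm isotropic voxels and 50 ms frames over a
#' 1000 ms cycle.
#'
#' The flow waveform is a truncated Fourier series
#' `Q(t) = meanFlow + sum_k amp_k * cos(2 pi k t / cycleMs + phase_k)` (ml/s);
#' the default approximates an aortic flow curve with systolic peak 400 ml/s
#' and stroke volume 95 ml.
#'
#' @slot tubeAxis unit vector along the tube.
#' @slot tubeCenter point on the tube axis, mm (world coordinates).
#' @slot radius tube radius, mm.
#' @slot gridShape integer length-3, voxels per axis.
#' @slot voxelSize length-3 numeric, mm.
#' @slot cycleMs cardiac cycle length, ms.
#' @slot nFrames number of reconstructed time frames.
#' @slot meanFlow mean flow, ml/s.
#' @slot harmonics k x 2 matrix, columns amplitude (ml/s) and phase (rad).
#' @slot venc velocity-encoding limit, mm/s.
#' @slot noiseSd per-component Gaussian velocity noise SD, mm/s.
#' @slot backgroundCoeffs length-4 numeric (a0, a1, a2, a3): offset added to
#'   the axial velocity component as `a0 + a1 x + a2 y + a3 z` (mm/s and
#'   mm/s per mm).
#' @slot seed integer RNG seed; part of the specification so a spec fully
#'   determines its dataset.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  slots = c(
    tubeAxis = "numeric",
    tubeCenter = "numeric",
    radius = "numeric",
    gridShape = "integer",
    voxelSize = "numeric",
    cycleMs = "numeric",
    nFrames = "integer",
    meanFlow = "numeric",
    harmonics = "matrix",
    venc = "numeric",
    noiseSd = "numeric",
    backgroundCoeffs = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@tubeAxis) != 3L ||
      abs(sqrt(sum(object@tubeAxis^2)) - 1) > 1e-8)
    return("tubeAxis must be a 3-vector of unit length")
  if (object@radius <= 0) return("radius must be > 0")
  if (length(object@gridShape) != 3L || any(object@gridShape < 2L))
    return("gridShape must be 3 integers >= 2")
  if (any(object@voxelSize <= 0)) return("voxelSize must be > 0")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  if (object@cycleMs <= 0) return("cycleMs must be > 0")
  if (object@venc <= 0) return("venc must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (ncol(object@harmonics) != 2L)
    return("harmonics must be a k x 2 matrix (amplitude ml/s, phase rad)")
  if (length(object@backgroundCoeffs) != 4L)
    return("backgroundCoeffs must have length 4 (a0, a1, a2, a3)")
  TRUE
})

#' Analytic ground truth accompanying a generated phantom
#'
#' @slot timeMs frame trigger times, ms.
#' @slot flowMlS analytic volumetric flow per frame, ml/s.
#' @slot strokeVolumeMl cyclic trapezoidal integral of the flow curve over
#'   one cycle, ml.
#' @slot peakFlowMlS maximum of the analytic flow curve, ml/s.
#' @slot bloodPoolMask logical 3-D array: voxels inside the tube lumen.
#' @slot staticMask logical 3-D array: static tissue (body minus lumen);
#'   disjoint from `bloodPoolMask` by construction.
#' @slot cycleMs cycle length, ms.
#' @export
setClass("GroundTruth",
  slots = c(
    timeMs = "numeric",
    flowMlS = "numeric",
    strokeVolumeMl = "numeric",
    peakFlowMlS = "numeric",
    bloodPoolMask = "array",
    staticMask = "array",
    cycleMs = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (any(object@bloodPoolMask & object@staticMask))
    return("bloodPoolMask and staticMask must be disjoint")
  if (length(object@timeMs) != length(object@flowMlS))
    return("timeMs and flowMlS lengths differ")
  TRUE
})

#' Oriented sampled 2D plane through a 4D dataset
#'
#' The plane carries an orthonormal right-handed triad `{uAxis, vAxis,
#' normal}` (uAxis x vAxis = normal), a pixel size and a pixel extent.
#' Pixel (i, j) (1-based) is centred at
#' `origin + (i - (nu+1)/2) * pixelSize * uAxis + (j - (nv+1)/2) * pixelSize * vAxis`,
#' i.e. the plane origin is the centre of the pixel grid.
#'
#' @slot origin mm point, centre of the plane.
#' @slot normal unit normal; through-plane velocity is `v . normal`.
#' @slot uAxis,vAxis in-plane orthonormal axes.
#' @slot pixelSize mm.
#' @slot extent integer length-2, pixels (nu, nv).
#'
#' @seealso [planeDefinition()], [reformatPlane()]
#' @export
setClass("PlaneDefinition",
  slots = c(
    origin = "numeric",
    normal = "numeric",
    uAxis = "numeric",
    vAxis = "numeric",
    pixelSize = "numeric",
    extent = "integer"
  )
)

setValidity("PlaneDefinition", function(object) {
  v3 <- function(x) length(x) == 3L && all(is.finite(x))
  if (!v3(object@origin) || !v3(object@normal) || !v3(object@uAxis) ||
      !v3(object@vAxis))
    return("origin, normal, uAxis, vAxis must be finite 3-vectors")
  tol <- 1e-12
  G <- rbind(object@uAxis, object@vAxis, object@normal)
  if (max(abs(G %*% t(G) - diag(3))) > tol)
    return("{uAxis, vAxis, normal} must be orthonormal to 1e-12")
  cr <- c(
    object@uAxis[2] * object@vAxis[3] - object@uAxis[3] * object@vAxis[2],
    object@uAxis[3] * object@vAxis[1] - object@uAxis[1] * object@vAxis[3],
    object@uAxis[1] * object@vAxis[2] - object@uAxis[2] * object@vAxis[1]
  )
  if (max(abs(cr - object@normal)) > tol)
    return("triad must be right-handed (uAxis x vAxis = normal) to 1e-12")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@extent) != 2L || any(object@extent < 2L))
    return("extent must be two integers >= 2")
  TRUE
})

#' Through-plane velocity series on a 2D plane
#'
#' Either an acquired 2D phase-contrast series or the result of reformatting
#' a [VelocityField4D-class] onto a [PlaneDefinition-class]. Pixels whose
#' interpolation stencil falls outside the source volume are flagged invalid
#' (`valid == FALSE`, values `NA`) rather than zero-filled.
#'
#' @slot vThrough numeric array `nu x nv x nt`, through-plane velocity mm/s
#'   (positive along the plane normal).
#' @slot magnitude numeric array `nu x nv x nt`.
#' @slot valid logical `nu x nv`, pixels inside the source volume.
#' @slot plane the [PlaneDefinition-class].
#' @slot pixelSize mm.
#' @slot triggerTimes,cycleMs,coveredMs,venc,coverage as in
#'   [VelocityField4D-class].
#' @export
setClass("Series2D",
  slots = c(
    vThrough = "array",
    magnitude = "array",
    valid = "matrix",
    plane = "PlaneDefinition",
    pixelSize = "numeric",
    triggerTimes = "numeric",
    cycleMs = "numeric",
    coveredMs = "numeric",
    venc = "numeric",
    coverage = "character"
  )
)

setValidity("Series2D", function(object) {
  dv <- dim(object@vThrough)
  if (length(dv) != 3L) return("vThrough must be nu x nv x nt")
  if (!all(dim(object@magnitude) == dv))
    return("magnitude dimensions must match vThrough")
  if (!all(dim(object@valid) == dv[1:2]))
    return("valid mask must be nu x nv")
  if (dv[3] < 2L) return("at least 2 frames are required")
  if (length(object@triggerTimes) != dv[3])
    return("length(triggerTimes) must equal frame count")
  if (any(diff(object@triggerTimes) <= 0))
    return("triggerTimes must be strictly increasing")
  if (!object@coverage %in% c("full", "truncated"))
    return("coverage must be 'full' or 'truncated'")
  TRUE
})

#' Closed vessel contour on a 2D plane
#'
#' A closed simple polygon in plane coordinates (mm, in the `uAxis`/`vAxis`
#' frame of the series' plane, origin at the plane centre). A single polygon
#' is used for all frames (static contour); per-frame contours are supported
#' by supplying one polygon per frame.
#'
#' @slot frames list of `n x 2` numeric matrices (columns u_mm, v_mm), either
#'   length 1 (static) or one per frame. Vertices are not repeated: the
#'   polygon closes from the last vertex back to the first.
#' @slot label vessel label, e.g. `"aorta"`, `"pulmonary"`, `"other"`.
#' @export
setClass("VesselContour",
  slots = c(frames = "list", label = "character")
)

setValidity("VesselContour", function(object) {
  if (length(object@frames) < 1L) return("at least one polygon is required")
  for (p in object@frames) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return("each polygon must be an n x 2 matrix with n >= 3")
    if (any(!is.finite(p))) return("polygon vertices must be finite")
    if (abs(.polygonArea(p)) <= 0) return("polygon must have positive area")
    if (!.polygonIsSimple(p)) return("polygon must be simple (non-self-intersecting)")
  }
  TRUE
})

#' Through-plane volumetric flow curve for one vessel
#'
#' @slot timeMs trigger times, ms.
#' @slot flowMlS flow per frame, ml/s.
#' @slot strokeVolumeMl integral of the flow curve over the cycle, ml
#'   (cyclic trapezoid for full coverage; open trapezoid over the covered
#'   support for truncated data).
#' @slot peakFlowMlS `max(flowMlS)`.
#' @slot coverage `"full"` or `"truncated"`.
#' @slot coveredMs covered portion of the cycle, ms.
#' @slot cycleMs cycle length, ms.
#' @export
setClass("FlowCurve",
  slots = c(
    timeMs = "numeric",
    flowMlS = "numeric",
    strokeVolumeMl = "numeric",
    peakFlowMlS = "numeric",
    coverage = "character",
    coveredMs = "numeric",
    cycleMs = "numeric"
  )
)

setValidity("FlowCurve", function(object) {
  if (length(object@timeMs) != length(object@flowMlS))
    return("timeMs and flowMlS lengths differ")
  if (length(object@flowMlS) &&
      abs(object@peakFlowMlS - max(object@flowMlS)) > 1e-9)
    return("peakFlowMlS must equal max(flowMlS)")
  TRUE
})

#' Particle emitter for pathline tracing
#'
#' @slot position emitter centre, mm (world coordinates).
#' @slot label region name (e.g. a cardiac chamber).
#' @slot releaseIntervalMs interval between particle releases, ms
#'   (default 10 ms over the full cycle).
#' @slot particlesPerRelease particles emitted per release.
#' @slot radiusMm emitter sphere radius; 0 releases all particles at the
#'   centre.
#' @export
setClass("EmitterSpec",
  slots = c(
    position = "numeric",
    label = "character",
    releaseIntervalMs = "numeric",
    particlesPerRelease = "integer",
    radiusMm = "numeric"
  )
)

setValidity("EmitterSpec", function(object) {
  if (length(object@position) != 3L || any(!is.finite(object@position)))
    return("position must be a finite 3-vector (mm)")
  if (object@releaseIntervalMs <= 0) return("releaseIntervalMs must be > 0")
  if (object@particlesPerRelease < 1L) return("particlesPerRelease must be >= 1")
  if (object@radiusMm < 0) return("radiusMm must be >= 0")
  TRUE
})

#' Set of traced pathlines with containment bookkeeping
#'
#' Positions of all particles at the stored output times, plus the geometry
#' needed to test blood-pool containment later. Grading fields
#' (`emitterStats`, `meanScore`) are filled by [gradeContainment()]; a
#' particle once flagged escaped never reverts.
#'
#' @slot positions numeric array `nParticles x 3 x nTimes` (mm); `NA` before
#'   a particle's release time.
#' @slot timesMs output times, ms.
#' @slot emitterId integer per particle.
#' @slot releaseMs release time per particle, ms.
#' @slot leftVolume logical per particle: left the sampled volume during
#'   integration (frozen at exit).
#' @slot insidePool logical `nParticles x nTimes` or empty until graded.
#' @slot emitterLabels labels of the emitters traced.
#' @slot origin,voxelSize,gridShape geometry of the source field (for mask
#'   lookups).
#' @slot emitterStats data.frame with per-emitter `fraction_escaped` and
#'   `grade` after grading.
#' @slot meanScore unweighted mean of emitter grades (NA until graded).
#' @export
setClass("PathlineSet",
  slots = c(
    positions = "array",
    timesMs = "numeric",
    emitterId = "integer",
    releaseMs = "numeric",
    leftVolume = "logical",
    insidePool = "matrix",
    emitterLabels = "character",
    origin = "numeric",
    voxelSize = "numeric",
    gridShape = "integer",
    emitterStats = "data.frame",
    meanScore = "numeric"
  )
)

setValidity("PathlineSet", function(object) {
  dp <- dim(object@positions)
  if (length(dp) != 3L || dp[2] != 3L)
    return("positions must be nParticles x 3 x nTimes")
  if (length(object@timesMs) != dp[3])
    return("timesMs length must match positions")
  if (length(object@emitterId) != dp[1] || length(object@releaseMs) != dp[1])
    return("per-particle slots must match particle count")
  act <- !is.na(object@positions)
  if (any(!is.finite(object@positions[act])))
    return("positions must be finite where defined")
  TRUE
})

#' First-order background-phase model
#'
#' Linear-in-space model `c0 + c1 x + c2 y + c3 z` per velocity component,
#' least-squares fitted to the time-averaged velocity of static tissue.
#'
#' @slot coefficients 4 x 3 numeric matrix; rows (intercept, x, y, z), one
#'   column per velocity component (mm/s and mm/s per mm).
#' @slot staticMask logical 3-D array used for the fit.
#' @slot fitResidualRms length-3 numeric, RMS residual per component, mm/s.
#' @slot nStatic number of voxels used.
#' @export
setClass("BackgroundModel",
  slots = c(
    coefficients = "matrix",
    staticMask = "array",
    fitResidualRms = "numeric",
    nStatic = "integer"
  )
)

setValidity("BackgroundModel", function(object) {
  if (!all(dim(object@coefficients) == c(4L, 3L)))
    return("coefficients must be a 4 x 3 matrix")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' Method-agreement report
#'
#' Linear regression of test on reference, Bland-Altman percent bias
#' (mean +/- SD of per-pair percent differences) and a paired two-sided
#' Wilcoxon signed-rank test. Percent differences use the reference value as
#' denominator by default (`100 (test - ref) / ref`); the classical pair-mean
#' convention is reported alongside.
#'
#' @slot n number of pairs.
#' @slot slope,intercept,rSquared ordinary least squares of test on reference.
#' @slot biasPercentMean,biasPercentSd reference-denominator percent bias.
#' @slot biasPercentMeanPairDenom,biasPercentSdPairDenom pair-mean denominator
#'   variant.
#' @slot denominator which convention `biasPercentMean` uses (`"reference"`).
#' @slot wilcoxonStatistic sum of positive-difference ranks (V).
#' @slot wilcoxonP two-sided p-value (exact for n <= 25 after dropping zero
#'   differences, normal approximation with continuity correction above).
#' @slot wilcoxonExact whether the exact null distribution was used.
#' @slot allZero TRUE when every paired difference is zero (p = 1 by
#'   convention).
#' @export
setClass("AgreementReport",
  slots = c(
    n = "integer",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    biasPercentMean = "numeric",
    biasPercentSd = "numeric",
    biasPercentMeanPairDenom = "numeric",
    biasPercentSdPairDenom = "numeric",
    denominator = "character",
    wilcoxonStatistic = "numeric",
    wilcoxonP = "numeric",
    wilcoxonExact = "logical",
    allZero = "logical"
  )
)

setValidity("AgreementReport", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  if (object@wilcoxonP <= 0 || object@wilcoxonP > 1)
    return("wilcoxonP must lie in (0, 1]")
  TRUE
})
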