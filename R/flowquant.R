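#' @include AllClasses.R utils.R reformat.R
NULL

## plane-local pixel-centre coordinates of a Series2D
.seriesPixelCoords <- function(series) {
  nu <- dim(series@vThrough)[1]; nv <- dim(series@vThrough)[2]
  h <- series@pixelSize
  list(u = (seq_len(nu) - (nu + 1) / 2) * h,
       v = (seq_len(nv) - (nv + 1) / 2) * h)
}

#' Threshold-based vessel segmentation on a 2D velocity series
#'
#' Stand-in for interactive semi-automatic vessel outlining: starting from a
#' seed inside the vessel, a connected region is grown on the peak-flow frame
#' (the frame of maximum absolute through-plane velocity at the seed) over
#' pixels whose absolute velocity is at least `thresholdFraction` times the
#' seed velocity and at least `minSpeedFraction` of VENC (the absolute floor
#' keeps near-zero static tissue from passing a purely relative threshold).
#' The region boundary is polygonised and used as a static contour for all
#' frames; edit or replace it via the contour CSV if needed.
#'
#' @param series a [Series2D-class].
#' @param seedPointMm length-2 seed in plane coordinates (mm, plane centre at
#'   0).
#' @param thresholdFraction relative threshold (default 0.1).
#' @param minSpeedFraction absolute floor as a fraction of VENC
#'   (default 0.02).
#' @param label vessel label.
#' @return A [VesselContour-class] (static, one polygon).
#' @export
segmentVessel <- function(series, seedPointMm, thresholdFraction = 0.1,
                          minSpeedFraction = 0.02, label = "other") {
  stopifnot(is(series, "Series2D"))
  pc <- .seriesPixelCoords(series)
  si <- which.min(abs(pc$u - seedPointMm[1]))
  sj <- which.min(abs(pc$v - seedPointMm[2]))
  if (!series@valid[si, sj])
    stop("segmentation error: seed falls on an invalid pixel")
  seedSeries <- series@vThrough[si, sj, ]
  fPeak <- which.max(abs(seedSeries))
  vabs <- abs(series@vThrough[, , fPeak])
  thr <- max(thresholdFraction * vabs[si, sj],
             minSpeedFraction * series@venc)
  nu <- nrow(vabs); nv <- ncol(vabs)
  ok <- !is.na(vabs) & vabs >= thr & series@valid
  if (!ok[si, sj])
    stop("segmentation error: empty region (seed below threshold)")
  ## 4-connected flood fill from the seed
  region <- matrix(FALSE, nu, nv)
  queue <- matrix(c(si, sj), ncol = 2)
  region[si, sj] <- TRUE
  while (nrow(queue) > 0) {
    i <- queue[, 1]; j <- queue[, 2]
    cand <- rbind(cbind(i - 1L, j), cbind(i + 1L, j),
                  cbind(i, j - 1L), cbind(i, j + 1L))
    keep <- cand[, 1] >= 1 & cand[, 1] <= nu & cand[, 2] >= 1 & cand[, 2] <= nv
    cand <- cand[keep, , drop = FALSE]
    keep <- ok[cand] & !region[cand]
    cand <- unique(cand[keep, , drop = FALSE])
    region[cand] <- TRUE
    queue <- cand
  }
  if (any(region[1, ]) || any(region[nu, ]) ||
      any(region[, 1]) || any(region[, nv]))
    warning("segmentation warning: region touches the image border")
  poly <- .traceRegionBoundary(region, pc$u, pc$v, series@pixelSize)
  new("VesselContour", frames = list(poly), label = label)
}

#' Compute a volumetric flow curve through a vessel contour
#'
#' Per frame, flow is the sum over pixels whose centre lies inside the
#' contour (even-odd rule; centres exactly on an edge count as inside) of
#' through-plane velocity times pixel area, converted to ml/s. Stroke volume
#' is the cyclic trapezoidal integral over `[0, cycleMs)` using the trigger
#' times for full-coverage series; truncated series are integrated over the
#' covered support only (open trapezoid plus zero-order hold to the coverage
#' end) and the coverage flag is propagated.
#'
#' @param series a [Series2D-class].
#' @param contour a [VesselContour-class] (static, or one polygon per frame).
#' @return A [FlowCurve-class].
#' @export
computeFlowCurve <- function(series, contour) {
  stopifnot(is(series, "Series2D"), is(contour, "VesselContour"))
  nt <- dim(series@vThrough)[3]
  static <- length(contour@frames) == 1L
  if (!static && length(contour@frames) != nt)
    stop("contour must have 1 polygon or one per frame")
  pc <- .seriesPixelCoords(series)
  nu <- length(pc$u); nv <- length(pc$v)
  px <- rep(pc$u, times = nv)
  py <- rep(pc$v, each = nu)
  areaMm2 <- series@pixelSize^2
  insideFor <- function(f) {
    poly <- contour@frames[[if (static) 1L else f]]
    matrix(.pointsInPolygon(px, py, poly), nu, nv)
  }
  insideStatic <- if (static) insideFor(1L) else NULL
  flow <- numeric(nt)
  for (f in seq_len(nt)) {
    inside <- if (static) insideStatic else insideFor(f)
    bad <- inside & !series@valid
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)
      stop("contour covers invalid pixels at (i,j): ",
           paste(apply(ij, 1, paste, collapse = ","), collapse = "; "))
    }
    flow[f] <- sum(series@vThrough[, , f][inside]) * areaMm2 / 1000
  }
  sv <- if (series@coverage == "full")
    .cyclicTrapz(series@triggerTimes, flow, series@cycleMs)
  else
    .truncatedTrapz(series@triggerTimes, flow, series@coveredMs)
  new("FlowCurve", timeMs = series@triggerTimes, flowMlS = flow,
      strokeVolumeMl = sv, peakFlowMlS = max(flow),
      coverage = series@coverage, coveredMs = series@coveredMs,
      cycleMs = series@cycleMs)
}

#' Signal-to-noise ratio with Rayleigh background correction
#'
#' `SNR = 0.655 x mean(magnitude in vessel ROI) / sd(magnitude in background
#' ROI)`. The 0.655 factor converts the standard deviation of
#' Rayleigh-distributed background magnitude (air, where only noise is
#' present) to the underlying Gaussian noise SD.
#'
#' @param x a [Series2D-class] or [VelocityField4D-class].
#' @param roiVessel,roiOutside logical masks over the spatial grid of `x`
#'   (`nu x nv` or `nx x ny x nz`); magnitudes are pooled over all frames.
#'   `roiOutside` must contain only air/background pixels.
#' @return SNR scalar.
#' @export
computeSNR <- function(x, roiVessel, roiOutside) {
  mag <- magnitudes(x)
  d <- dim(mag)
  nsp <- length(d) - 1L
  if (!all(dim(roiVessel) == d[seq_len(nsp)]) ||
      !all(dim(roiOutside) == d[seq_len(nsp)]))
    stop("ROI dimensions must match the spatial grid")
  if (!any(roiVessel) || !any(roiOutside))
    stop("both ROIs must be nonempty")
  nt <- d[length(d)]
  mm <- matrix(mag, ncol = nt)
  sig <- as.vector(mm[as.vector(roiVessel), ])
  noi <- as.vector(mm[as.vector(roiOutside), ])
  sdN <- stats::sd(noi)
  if (sdN == 0)
    stop("degenerate-noise error: background magnitude has zero variance")
  0.655 * mean(sig) / sdN
}

#' Pulmonary-to-systemic flow ratio (QP/QS)
#'
#' Ratio of the pulmonary to the systemic stroke volume; approximately 1 in
#' subjects without shunts, so a conservation check for flow pipelines.
#'
#' @param pulmonary,systemic [FlowCurve-class] objects with positive stroke
#'   volumes.
#' @return The ratio.
#' @export
computeQpQs <- function(pulmonary, systemic) {
  stopifnot(is(pulmonary, "FlowCurve"), is(systemic, "FlowCurve"))
  svp <- strokeVolume(pulmonary)
  svs <- strokeVolume(systemic)
  if (svp <= 0 || svs <= 0)
    stop("QP/QS requires positive stroke volumes")
  svp / svs
}

#' Construct a vessel contour from vertices
#'
#' @param vertices `n x 2` matrix of (u_mm, v_mm) plane coordinates, or a
#'   list of such matrices (one per frame).
#' @param label vessel label.
#' @return A [VesselContour-class].
#' @export
vesselContour <- function(vertices, label = "other") {
  frames <- if (is.list(vertices)) vertices else list(vertices)
  frames <- lapply(frames, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("u_mm", "v_mm")
    p
  })
  new("VesselContour", frames = frames, label = label)
}

#' Area of a contour polygon
#'
#' @param contour a [VesselContour-class].
#' @param frame which polygon (default first).
#' @return Area in mm^2.
#' @export
contourArea <- function(contour, frame = 1L) {
  abs(.polygonArea(contour@frames[[min(frame, length(contour@frames))]]))
}
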