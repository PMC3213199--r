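## Builders for analytic fields and small phantoms shared across tests.

## Steady rigid-rotation field about the z axis: v = omega x r (mm/s, omega
## rad/s). Trilinear interpolation reproduces this affine field exactly, so
## pathline integration error is purely the time-stepper's.
rotationField <- function(omega = 2 * pi, gridShape = c(33L, 33L, 33L),
                          voxelSize = 3, nFrames = 3L, cycleMs = 1000,
                          venc = 1e6) {
  origin <- -(gridShape - 1) / 2 * rep(voxelSize, length.out = 3)
  xs <- origin[1] + (seq_len(gridShape[1]) - 1) * voxelSize
  ys <- origin[2] + (seq_len(gridShape[2]) - 1) * voxelSize
  vx <- outer(xs, ys, function(x, y) -omega * y)
  vy <- outer(xs, ys, function(x, y) omega * x)
  vel <- array(0, dim = c(gridShape, nFrames, 3L))
  for (f in seq_len(nFrames)) {
    for (z in seq_len(gridShape[3])) {
      vel[, , z, f, 1] <- vx
      vel[, , z, f, 2] <- vy
    }
  }
  velocityField4D(vel, voxelSize = voxelSize, origin = origin,
                  triggerTimes = (seq_len(nFrames) - 1) * cycleMs / nFrames,
                  cycleMs = cycleMs, venc = venc)
}

## Spatially uniform steady field.
uniformField <- function(v0, gridShape = c(12L, 12L, 12L), voxelSize = 3,
                         nFrames = 2L, cycleMs = 1000, venc = 1e6) {
  origin <- -(gridShape - 1) / 2 * rep(voxelSize, length.out = 3)
  vel <- array(0, dim = c(gridShape, nFrames, 3L))
  for (comp in 1:3) vel[, , , , comp] <- v0[comp]
  velocityField4D(vel, voxelSize = voxelSize, origin = origin,
                  triggerTimes = (seq_len(nFrames) - 1) * cycleMs / nFrames,
                  cycleMs = cycleMs, venc = venc)
}

## Linear (affine) steady field v(x) = A %*% x + b.
linearField <- function(A, b = c(0, 0, 0), gridShape = c(17L, 17L, 17L),
                        voxelSize = 3, nFrames = 2L, cycleMs = 1000,
                        venc = 1e6) {
  origin <- -(gridShape - 1) / 2 * rep(voxelSize, length.out = 3)
  co <- expand.grid(
    x = origin[1] + (seq_len(gridShape[1]) - 1) * voxelSize,
    y = origin[2] + (seq_len(gridShape[2]) - 1) * voxelSize,
    z = origin[3] + (seq_len(gridShape[3]) - 1) * voxelSize)
  V <- as.matrix(co) %*% t(A) + matrix(b, nrow(co), 3, byrow = TRUE)
  vel <- array(0, dim = c(gridShape, nFrames, 3L))
  for (comp in 1:3) for (f in seq_len(nFrames))
    vel[, , , f, comp] <- array(V[, comp], dim = gridShape)
  velocityField4D(vel, voxelSize = voxelSize, origin = origin,
                  triggerTimes = (seq_len(nFrames) - 1) * cycleMs / nFrames,
                  cycleMs = cycleMs, venc = venc)
}

## Constant-flow phantom spec (no harmonics): Q(t) = meanFlow.
constantFlowSpec <- function(meanFlow, radius = 10, venc = 2000, ...) {
  phantomSpec(meanFlow = meanFlow,
              harmonics = matrix(numeric(0), 0, 2), radius = radius,
              venc = venc, ...)
}

## Tilted measurement plane through the origin (normal rotated off the tube
## axis by `tiltRad` about x).
tiltedPlane <- function(tiltRad = 0.26, pixelSize = 1.5,
                        extent = c(40L, 40L)) {
  planeDefinition(c(0, 0, 0),
                  normal = c(0, sin(tiltRad), cos(tiltRad)),
                  pixelSize = pixelSize, extent = extent)
}

## Measured stroke volume of a field through a plane via threshold
## segmentation; returns the FlowCurve.
measureFlow <- function(field, plane = tiltedPlane(), seedMm = c(0, 0),
                        thresholdFraction = 0.1, contour = NULL) {
  s <- reformatPlane(field, plane)
  if (is.null(contour))
    contour <- segmentVessel(s, seedMm, thresholdFraction)
  computeFlowCurve(s, contour)
}
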