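## build a synthetic Series2D directly (uniform through-plane velocity)
makeSeries <- function(v, nu = 30L, nv = 30L, nt = 4L, pixelSize = 1,
                       cycleMs = 1000, venc = 2000, mag = 100) {
  plane <- planeDefinition(c(0, 0, 0), c(0, 0, 1), pixelSize = pixelSize,
                           extent = c(nu, nv))
  vth <- array(v, dim = c(nu, nv, nt))
  new("Series2D", vThrough = vth,
      magnitude = array(mag, dim = c(nu, nv, nt)),
      valid = matrix(TRUE, nu, nv), plane = plane, pixelSize = pixelSize,
      triggerTimes = (seq_len(nt) - 1) * cycleMs / nt, cycleMs = cycleMs,
      coveredMs = cycleMs, venc = venc, coverage = "full")
}

squareContour <- function(halfSide) {
  vesselContour(rbind(c(-halfSide, -halfSide), c(halfSide, -halfSide),
                      c(halfSide, halfSide), c(-halfSide, halfSide)))
}

test_that("uniform velocity over a known area gives exact flow and SV", {
  ## 100 mm/s over 400 mm^2 -> 40 ml/s; constant over a 1 s cycle -> 40 ml
  s <- makeSeries(100)
  ct <- squareContour(10)   # 20 x 20 mm, pixel centres at +/-0.5, ...
  fc <- computeFlowCurve(s, ct)
  expect_equal(flowValues(fc), rep(40, 4))
  expect_equal(strokeVolume(fc), 40)
  expect_equal(peakFlow(fc), 40)
})

test_that("flow and SV are exactly linear in velocity and sign", {
  p <- generatePhantom(phantomSpec())
  s <- reformatPlane(p$field, tiltedPlane())
  ct <- segmentVessel(s, c(0, 0))
  fc <- computeFlowCurve(s, ct)
  k <- 2.5
  sk <- s; sk@vThrough <- k * s@vThrough
  fck <- computeFlowCurve(sk, ct)
  expect_equal(flowValues(fck), k * flowValues(fc))
  expect_equal(strokeVolume(fck), k * strokeVolume(fc))
  sneg <- s; sneg@vThrough <- -s@vThrough
  fcn <- computeFlowCurve(sneg, ct)
  expect_equal(flowValues(fcn), -flowValues(fc))
  expect_equal(strokeVolume(fcn), -strokeVolume(fc))
})

test_that("Poiseuille flux is recovered to 2% on a fine grid", {
  ## R = 10 mm, v_max = 1000 mm/s -> Q = v_max pi R^2 / 2 = 157.08 ml/s;
  ## 1.5 mm voxels so the trilinear sampling error of the parabolic
  ## profile (O(h^2)) sits below the 2% budget
  q <- 1000 * pi * 100 / 2 / 1000
  p <- generatePhantom(constantFlowSpec(meanFlow = q, radius = 10,
                                        gridShape = c(33L, 33L, 33L),
                                        voxelSize = 1.5, nFrames = 4L))
  plane <- planeDefinition(c(0, 0, 0), c(0, 0, 1), pixelSize = 1,
                           extent = c(30L, 30L))
  s <- reformatPlane(p$field, plane)
  fc <- computeFlowCurve(s, segmentVessel(s, c(0, 0),
                                          thresholdFraction = 0.05))
  expect_equal(flowValues(fc)[1], q, tolerance = 0.02)
})

test_that("threshold segmentation is deterministic and area-accurate", {
  p <- generatePhantom(constantFlowSpec(meanFlow = 157.0796, radius = 10,
                                        gridShape = c(33L, 33L, 33L)))
  plane <- planeDefinition(c(0, 0, 0), c(0, 0, 1), pixelSize = 1,
                           extent = c(36L, 36L))
  s <- reformatPlane(p$field, plane)
  ct1 <- segmentVessel(s, c(0, 0), thresholdFraction = 0.1)
  ct2 <- segmentVessel(s, c(0.3, -0.2), thresholdFraction = 0.1)
  expect_identical(ct1@frames[[1]], ct2@frames[[1]])
  ## area within one pixel-ring (~2 pi R h) of pi R^2
  expect_lt(abs(contourArea(ct1) - pi * 100), 2 * pi * 10 * 1)
  ## seeding in static tissue finds nothing above the absolute floor
  expect_error(segmentVessel(s, c(16, 16)), "empty region")
})

test_that("segmentation warns when the region touches the border", {
  p <- generatePhantom(constantFlowSpec(meanFlow = 157.0796, radius = 10,
                                        gridShape = c(33L, 33L, 33L)))
  plane <- planeDefinition(c(0, 0, 0), c(0, 0, 1), pixelSize = 1,
                           extent = c(14L, 14L))   # smaller than the vessel
  s <- reformatPlane(p$field, plane)
  expect_warning(segmentVessel(s, c(0, 0)), "border")
})

test_that("contours over invalid pixels are rejected with their indices", {
  p <- generatePhantom(phantomSpec())
  ## plane centred at the volume edge: part of the grid falls outside
  plane <- planeDefinition(c(44, 0, 0), c(0, 0, 1), pixelSize = 1.5,
                           extent = c(20L, 20L))
  s <- reformatPlane(p$field, plane)
  expect_true(any(!validPixels(s)))
  big <- vesselContour(rbind(c(-14, -14), c(14, -14), c(14, 14), c(-14, 14)))
  expect_error(computeFlowCurve(s, big), "invalid pixels")
  ## fully outside the volume is a geometry error at reformat time
  far <- planeDefinition(c(500, 500, 500), c(0, 0, 1), pixelSize = 1,
                         extent = c(4L, 4L))
  expect_error(reformatPlane(p$field, far), "geometry error")
})

test_that("SNR follows the Rayleigh-corrected magnitude formula", {
  ## mean vessel magnitude 100, background SD 10 -> 0.655 * 100 / 10 = 6.55
  nu <- 20L; nv <- 20L; nt <- 2L
  s <- makeSeries(0, nu = nu, nv = nv, nt = nt)
  set.seed(1)
  noise <- array(rnorm(nu * nv * nt, 0, 10), dim = c(nu, nv, nt))
  mag <- array(100, dim = c(nu, nv, nt))
  mag[11:20, , ] <- noise[11:20, , ]
  s@magnitude <- mag
  roiV <- matrix(FALSE, nu, nv); roiV[1:10, ] <- TRUE
  roiO <- matrix(FALSE, nu, nv); roiO[11:20, ] <- TRUE
  snr <- computeSNR(s, roiV, roiO)
  expect_equal(snr, 0.655 * 100 / sd(as.vector(noise[11:20, , ])),
               tolerance = 1e-12)
  ## zero background variance is a guarded error
  s@magnitude[11:20, , ] <- 0
  expect_error(computeSNR(s, roiV, roiO), "degenerate-noise")
})

test_that("doubling velocity noise halves the measured phantom SNR", {
  snrOf <- function(noiseSd, seed) {
    p <- generatePhantom(phantomSpec(noiseSd = noiseSd, seed = seed))
    body <- p$truth@bloodPoolMask | p$truth@staticMask
    expect_gt(sum(!body), 1000)
    computeSNR(p$field, p$truth@bloodPoolMask, !body)
  }
  s30 <- snrOf(30, 2L)
  s60 <- snrOf(60, 2L)
  expect_equal(s30 / s60, 2, tolerance = 0.1)
  ## absolute level: sigma_v = sqrt(2) venc / (pi SNR)
  expect_equal(s60, sqrt(2) * 2000 / (pi * 60), tolerance = 0.1)
})

test_that("QP/QS is the stroke-volume ratio with positivity guards", {
  s <- makeSeries(100)
  ct <- squareContour(10)
  fc <- computeFlowCurve(s, ct)
  expect_equal(computeQpQs(fc, fc), 1.0)
  s2 <- makeSeries(103)
  expect_equal(computeQpQs(computeFlowCurve(s2, ct), fc), 1.03)
  sneg <- makeSeries(-100)
  expect_error(computeQpQs(computeFlowCurve(sneg, ct), fc), "positive")
})

test_that("flux error converges as the sampling grid is refined", {
  ## integrate the reformatted field over a fixed circular contour while
  ## refining voxel and pixel size together: the error is dominated by the
  ## O(h^2) trilinear sampling error of the parabolic profile
  q <- 157.0796
  circle <- vesselContour(cbind(10.8 * cos(2 * pi * (0:63) / 64),
                                10.8 * sin(2 * pi * (0:63) / 64)))
  err <- sapply(c(3, 1.5, 0.75), function(h) {
    p <- generatePhantom(constantFlowSpec(
      meanFlow = q, radius = 10, voxelSize = h,
      gridShape = rep(as.integer(2 * ceiling(15 / h) + 3), 3), nFrames = 2L))
    plane <- planeDefinition(c(0, 0, 0), c(0, 0, 1), pixelSize = h / 3,
                             extent = as.integer(c(28, 28) / (h / 3)))
    s <- reformatPlane(p$field, plane)
    abs(flowValues(computeFlowCurve(s, circle))[1] - q) / q
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
  ## near-quadratic: a 4x refinement gains well over one order of magnitude
  expect_gt(err[1] / err[3], 8)
})
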