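test_that("static tissue is separated from pulsatile lumen without noise", {
  p <- generatePhantom(phantomSpec())
  ## zero noise: static tissue has exactly zero temporal speed variation
  mask <- detectStaticTissue(p$field, speedSdThreshold = 1)
  expect_true(all(mask[p$truth@staticMask]))
  ## the lumen core varies strongly over the cycle and must not be marked
  core <- p$truth@bloodPoolMask
  d <- dim(core)
  co <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  org <- gridOrigin(p$field); vs <- voxelSize(p$field)
  r <- sqrt((org[1] + (co$i - 1) * vs[1])^2 + (org[2] + (co$j - 1) * vs[2])^2)
  coreIdx <- array(r < 0.9 * 12, dim = d) & core
  expect_false(any(mask[coreIdx]))
})

test_that("an all-moving field yields the documented empty-mask error", {
  p <- generatePhantom(phantomSpec())
  vel <- p$field@velocity
  nt <- dim(vel)[4]
  for (f in seq_len(nt)) vel[, , , f, 3] <- 500 * sin(2 * pi * f / nt) + 600
  allMoving <- velocityField4D(vel, p$field@magnitude,
                               voxelSize = voxelSize(p$field),
                               origin = gridOrigin(p$field),
                               triggerTimes = triggerTimes(p$field),
                               cycleMs = cycleMs(p$field), venc = 2000)
  expect_error(detectStaticTissue(allMoving, speedSdThreshold = 10),
               "static mask")
})

test_that("noisy static tissue is detected at the expected rate", {
  ## speed SD under 3-component Gaussian noise (sd 5) stays well below a
  ## 15 mm/s threshold for essentially all static voxels
  p <- generatePhantom(phantomSpec(noiseSd = 5, seed = 11L))
  mask <- detectStaticTissue(p$field, speedSdThreshold = 15)
  rate <- sum(mask & p$truth@staticMask) / sum(p$truth@staticMask)
  expect_gte(rate, 0.99)
})

test_that("injected first-order background coefficients are recovered", {
  coefs <- c(10, 0.5, -0.3, 0.2)
  p <- generatePhantom(phantomSpec(backgroundCoeffs = coefs))
  mask <- detectStaticTissue(p$field, speedSdThreshold = 1)
  model <- fitBackground(p$field, mask)
  expect_equal(unname(model@coefficients[, 3]), coefs, tolerance = 1e-9)
  expect_equal(max(abs(model@coefficients[, 1:2])), 0, tolerance = 1e-9)
  expect_lt(max(model@fitResidualRms), 1e-9)

  ## zero-offset phantom: all coefficients vanish
  p0 <- generatePhantom(phantomSpec())
  m0 <- fitBackground(p0$field, detectStaticTissue(p0$field, 1))
  expect_equal(max(abs(m0@coefficients)), 0, tolerance = 1e-9)
})

test_that("noisy background fit recovers coefficients within 3 SE", {
  coefs <- c(10, 0.5, -0.3, 0.2)
  sdv <- 5
  p <- generatePhantom(phantomSpec(backgroundCoeffs = coefs, noiseSd = sdv,
                                   seed = 3L))
  mask <- p$truth@staticMask
  expect_gt(sum(mask), 5e3)
  model <- fitBackground(p$field, mask)
  ## LS covariance: sigma^2 (X'X)^{-1} with sigma the SD of the
  ## time-averaged noise
  idx <- which(mask)
  d <- dim(mask)
  org <- gridOrigin(p$field); vs <- voxelSize(p$field)
  ai <- arrayInd(idx, d)
  X <- cbind(1, org[1] + (ai[, 1] - 1) * vs[1],
             org[2] + (ai[, 2] - 1) * vs[2],
             org[3] + (ai[, 3] - 1) * vs[3])
  se <- sqrt(diag(solve(crossprod(X))) * sdv^2 / nFrames(p$field))
  expect_true(all(abs(model@coefficients[, 3] - coefs) < 3 * se))
})

test_that("degenerate static masks raise rank-deficiency errors", {
  p <- generatePhantom(phantomSpec())
  few <- array(FALSE, dim(p$truth@staticMask))
  few[2, 2, 2] <- TRUE
  expect_error(fitBackground(p$field, few), "at least 4")
  plane <- array(FALSE, dim(p$truth@staticMask))
  plane[, , 2] <- p$truth@staticMask[, , 2]   # coplanar voxels only
  expect_error(fitBackground(p$field, plane), "rank-deficiency")
})

test_that("background correction is exactly invertible and zeroes statics", {
  coefs <- c(60, 0.3, -0.25, 0.2)
  p <- generatePhantom(phantomSpec(backgroundCoeffs = coefs))
  mask <- detectStaticTissue(p$field, speedSdThreshold = 1)
  model <- fitBackground(p$field, mask)
  corrected <- correctBackground(p$field, model)
  stat <- which(p$truth@staticMask)
  for (f in c(1, 10))
    expect_lt(max(abs(corrected@velocity[, , , f, 3][stat])), 1e-6)
  restored <- correctBackground(corrected, model, add = TRUE)
  expect_equal(restored@velocity, p$field@velocity, tolerance = 1e-12)
  ## zero model is the identity
  zero <- model
  zero@coefficients[] <- 0
  expect_equal(correctBackground(p$field, zero)@velocity, p$field@velocity)
})

test_that("background correction commutes with reformatting", {
  ## the fitted model is linear in space, so trilinear interpolation of the
  ## correction equals the correction at the interpolated point
  coefs <- c(60, 0.3, -0.25, 0.2)
  p <- generatePhantom(phantomSpec(backgroundCoeffs = coefs))
  model <- fitBackground(p$field, detectStaticTissue(p$field, 1))
  plane <- tiltedPlane(pixelSize = 2.5, extent = c(20L, 20L))
  sRaw <- reformatPlane(p$field, plane)
  sCor <- reformatPlane(correctBackground(p$field, model), plane)
  ## modelled axial offset at each pixel position, projected on the normal
  nu <- plane@extent[1]; nv <- plane@extent[2]; h <- plane@pixelSize
  us <- (seq_len(nu) - (nu + 1) / 2) * h
  vs <- (seq_len(nv) - (nv + 1) / 2) * h
  P <- matrix(plane@origin, nu * nv, 3, byrow = TRUE) +
    outer(rep(us, nv), plane@uAxis) + outer(rep(vs, each = nu), plane@vAxis)
  bg <- coefs[1] + P %*% coefs[2:4]
  off <- matrix(bg * plane@normal[3], nu, nv)
  for (f in c(1, 5))
    expect_equal(sCor@vThrough[, , f], sRaw@vThrough[, , f] - off,
                 tolerance = 1e-9)
})

test_that("wrap-then-unwrap round-trips series with sub-VENC true jumps", {
  vencV <- 800
  set.seed(5)
  nf <- 8
  ## brute-force oracle: over all per-frame 2*VENC shifts, minimise the
  ## cyclic total variation of the reconstruction, anchored at the min-|v|
  ## frame (which a single shift cannot move back inside the VENC range)
  oracle <- function(w) {
    ks <- as.matrix(expand.grid(rep(list(-1:1), length(w))))
    best <- NULL; bestTv <- Inf
    for (r in seq_len(nrow(ks))) {
      cand <- w + 2 * vencV * ks[r, ]
      if (abs(cand[which.min(abs(w))]) > vencV) next
      tv <- sum(abs(diff(c(cand, cand[1]))))
      if (tv < bestTv) { bestTv <- tv; best <- cand }
    }
    unname(best)
  }
  for (amp in c(850, 920, 1000)) {
    ## periodic series crossing +/-VENC through sub-VENC increments
    phi <- runif(1, 0, 2 * pi)
    true <- amp * sin(2 * pi * (0:(nf - 1)) / nf + phi)
    w <- wrapToVenc(true, vencV)
    expect_false(isTRUE(all.equal(w, true)))   # aliasing did occur
    vel <- array(0, dim = c(2, 2, 2, nf, 3))
    for (f in 1:nf) vel[, , , f, 3] <- w[f]
    fld <- velocityField4D(vel, voxelSize = 3, origin = c(0, 0, 0),
                           triggerTimes = (0:(nf - 1)) * 100, cycleMs = 1000,
                           venc = vencV)
    un <- unwrapVelocity(fld)
    got <- un@velocity[1, 1, 1, , 3]
    expect_equal(got, true, tolerance = 1e-9)
    expect_equal(got, oracle(w), tolerance = 1e-9)
    ## projection property: wrapping the unwrapped equals the stored data
    expect_equal(wrapToVenc(got, vencV), w, tolerance = 1e-9)
  }
})

test_that("unwrapping is idempotent and the identity on clean data", {
  p <- generatePhantom(phantomSpec())   # peak 1768 mm/s < VENC 2000
  un <- unwrapVelocity(p$field)
  expect_equal(un@velocity, p$field@velocity)
  expect_equal(processingStage(un), "unwrapped")
  expect_equal(unwrapReport(un)$nUnwrapped, 0L)
  un2 <- unwrapVelocity(un)
  expect_equal(un2@velocity, un@velocity)
})

test_that("unwrapping restores stroke volume of an aliased phantom", {
  ## VENC at 80% of the peak centerline velocity aliases the systolic core
  peakV <- 2 * 400 * 1000 / (pi * 144)
  spec <- phantomSpec(venc = 0.8 * peakV)
  p <- generatePhantom(spec)
  un <- unwrapVelocity(p$field)
  svTrue <- strokeVolume(p$truth)
  fcWith <- measureFlow(un)
  errWith <- abs(strokeVolume(fcWith) - svTrue) / svTrue
  expect_lt(errWith, 0.03)
  ## same contour on the aliased data: large error
  sWrap <- reformatPlane(p$field, tiltedPlane())
  ctr <- segmentVessel(reformatPlane(un, tiltedPlane()), c(0, 0))
  errWithout <- abs(strokeVolume(computeFlowCurve(sWrap, ctr)) - svTrue) / svTrue
  expect_gt(errWithout, 0.10)
  expect_gt(unwrapReport(un)$nUnwrapped, 0)
})
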