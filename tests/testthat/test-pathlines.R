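test_that("constant uniform flow translates particles exactly", {
  f <- uniformField(c(10, 0, 0))
  em <- emitterSpec(c(0, 0, 0), releaseIntervalMs = 1000)
  paths <- tracePathlines(f, list(em), stepMs = 10, durationMs = 100)
  endPos <- paths@positions[1, , length(paths@timesMs)]
  expect_equal(endPos, c(1, 0, 0), tolerance = 1e-12)
})

test_that("RK4 closes a rigid-rotation orbit to 1e-6 of its radius", {
  f <- rotationField(omega = 2 * pi)   # one revolution per 1000 ms
  r0 <- c(20, 0, 0)
  em <- emitterSpec(r0, releaseIntervalMs = 2000)
  paths <- tracePathlines(f, list(em), stepMs = 1, durationMs = 1000,
                          outputEveryMs = 100)
  traj <- t(paths@positions[1, , ])
  endErr <- sqrt(sum((traj[nrow(traj), ] - r0)^2))
  expect_lt(endErr, 1e-6 * 20)
  ## radius drift along the orbit
  radii <- sqrt(traj[, 1]^2 + traj[, 2]^2)
  expect_lt(max(abs(radii - 20)) / 20, 1e-6)
})

test_that("halving the step shows 4th-order convergence", {
  f <- rotationField(omega = 2 * pi)
  r0 <- c(20, 0, 0)
  em <- emitterSpec(r0, releaseIntervalMs = 2000)
  errAt <- function(h) {
    paths <- tracePathlines(f, list(em), stepMs = h, durationMs = 1000,
                            outputEveryMs = 1000)
    sqrt(sum((paths@positions[1, , length(paths@timesMs)] - r0)^2))
  }
  errs <- sapply(c(8, 4, 2), errAt)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(abs(orders - 4) < 0.3))
})

test_that("forward-backward integration on a steady field returns home", {
  f <- rotationField(omega = 2 * pi)
  em <- emitterSpec(c(20, 0, 0), releaseIntervalMs = 2000)
  fwd <- tracePathlines(f, list(em), stepMs = 1, durationMs = 250,
                        outputEveryMs = 250)
  mid <- fwd@positions[1, , length(fwd@timesMs)]
  fneg <- f
  fneg@velocity <- -f@velocity
  back <- tracePathlines(fneg, list(emitterSpec(mid, releaseIntervalMs = 2000)),
                         stepMs = 1, durationMs = 250, outputEveryMs = 250)
  endPos <- back@positions[1, , length(back@timesMs)]
  expect_lt(sqrt(sum((endPos - c(20, 0, 0))^2)), 2 * 1e-6 * 20)
})

test_that("particles leaving the volume are frozen and flagged", {
  f <- uniformField(c(100, 0, 0), gridShape = c(8L, 8L, 8L))  # 21 mm wide
  em <- emitterSpec(c(0, 0, 0), releaseIntervalMs = 2000)
  paths <- tracePathlines(f, list(em), stepMs = 1, durationMs = 1000,
                          outputEveryMs = 50)
  expect_true(paths@leftVolume[1])
  traj <- t(paths@positions[1, , ])
  expect_true(all(is.finite(traj)))
  expect_lt(max(traj[, 1]), 11)   # frozen at the boundary, not advected on
})

test_that("containment grading matches the 0-3 scale and mean score", {
  ## rotating flow inside a generous cylinder mask: nothing escapes
  f <- rotationField(omega = 2 * pi)
  gs <- dim(f@velocity)[1:3]
  co <- expand.grid(i = 1:gs[1], j = 1:gs[2], k = 1:gs[3])
  x <- f@origin[1] + (co$i - 1) * 3
  y <- f@origin[2] + (co$j - 1) * 3
  cyl <- array(sqrt(x^2 + y^2) <= 35, dim = gs)
  ems <- list(emitterSpec(c(20, 0, 0), label = "a", releaseIntervalMs = 100),
              emitterSpec(c(0, -15, 0), label = "b", releaseIntervalMs = 100))
  paths <- tracePathlines(f, ems, stepMs = 2, durationMs = 1000,
                          outputEveryMs = 20)
  graded <- gradeContainment(paths, cyl)
  expect_equal(unname(emitterGrades(graded)), c(0L, 0L))
  expect_equal(meanQualityScore(graded), 0)
  ## uniformly outward flow escapes everywhere: grade 3
  fo <- uniformField(c(200, 0, 0), gridShape = c(12L, 12L, 12L))
  small <- array(FALSE, dim = c(12L, 12L, 12L))
  small[5:8, 5:8, 5:8] <- TRUE
  po <- tracePathlines(fo, list(emitterSpec(c(0, 0, 0),
                                            releaseIntervalMs = 100)),
                       stepMs = 2, durationMs = 1000, outputEveryMs = 20)
  go <- gradeContainment(po, small)
  expect_equal(unname(emitterGrades(go)), 3L)
})

test_that("grading thresholds are monotone and average per the scale", {
  ## construct pathline sets directly with controlled escape fractions
  mkPaths <- function(fracEscaped, nPerEmitter = 20L) {
    ne <- length(fracEscaped)
    np <- ne * nPerEmitter
    pos <- array(0, dim = c(np, 3L, 2L))
    emId <- rep(seq_len(ne), each = nPerEmitter)
    for (e in seq_len(ne)) {
      nEsc <- round(fracEscaped[e] * nPerEmitter)
      rows <- which(emId == e)[seq_len(nEsc)]
      pos[rows, 1, 2] <- 100   # outside the mask at the second sample
    }
    new("PathlineSet", positions = pos, timesMs = c(0, 10),
        emitterId = emId, releaseMs = rep(0, np),
        leftVolume = rep(FALSE, np), insidePool = matrix(logical(0), 0, 0),
        emitterLabels = paste0("e", seq_len(ne)),
        origin = c(-15, -15, -15), voxelSize = c(3, 3, 3),
        gridShape = c(11L, 11L, 11L),
        emitterStats = data.frame(), meanScore = NA_real_)
  }
  mask <- array(TRUE, dim = c(11L, 11L, 11L))
  g <- gradeContainment(mkPaths(c(0, 0.05, 0.05, 0.05)), mask)
  expect_equal(unname(emitterGrades(g)), c(0L, 1L, 1L, 1L))
  expect_equal(meanQualityScore(g), 0.75)
  ## fractions at and beyond each threshold map to increasing grades
  g2 <- gradeContainment(mkPaths(c(0, 0.05, 0.2, 0.5)), mask)
  expect_equal(unname(emitterGrades(g2)), c(0L, 1L, 2L, 3L))
  fr <- seq(0, 1, by = 0.05)
  gAll <- gradeContainment(mkPaths(fr), mask)
  expect_true(all(diff(unname(emitterGrades(gAll))) >= 0))
})

test_that("emitters outside the volume and empty masks are errors", {
  f <- uniformField(c(10, 0, 0))
  expect_error(tracePathlines(f, list(emitterSpec(c(500, 0, 0)))),
               "geometry error")
  em <- emitterSpec(c(0, 0, 0), releaseIntervalMs = 500)
  paths <- tracePathlines(f, list(em), stepMs = 10, durationMs = 100)
  expect_error(gradeContainment(paths, array(FALSE, dim(f@velocity)[1:3])),
               "empty")
})

test_that("truncated-coverage fields clamp in time with a warning", {
  p <- generatePhantom(phantomSpec())
  tr <- applyProspectiveTruncation(p$field, 0.85)
  em <- emitterSpec(c(20, 20, 0), releaseIntervalMs = 500)
  expect_warning(
    tracePathlines(tr, list(em), stepMs = 10, durationMs = 100),
    "clamped")
})
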