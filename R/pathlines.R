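#' @include AllClasses.R utils.R
NULL

#' Construct a particle emitter
#'
#' @param position emitter centre, mm (world coordinates).
#' @param label region name.
#' @param releaseIntervalMs interval between releases, ms (default 10).
#' @param particlesPerRelease particles per release (default 1).
#' @param radiusMm emitter sphere radius (default 0: point source).
#' @return An [EmitterSpec-class].
#' @export
emitterSpec <- function(position, label = "emitter", releaseIntervalMs = 10,
                        particlesPerRelease = 1L, radiusMm = 0) {
  new("EmitterSpec", position = as.numeric(position), label = label,
      releaseIntervalMs = as.numeric(releaseIntervalMs),
      particlesPerRelease = as.integer(particlesPerRelease),
      radiusMm = as.numeric(radiusMm))
}

## Velocity (mm/s) at world points, trilinear in space and linear in time;
## time is periodic over the cycle for full-coverage fields and clamped to
## the sampled range for truncated fields. vlist[[f]][[comp]] are per-frame
## per-component 3-D arrays (pre-split for speed).
.velocityAt <- function(vlist, tt, cycleMs, coverage, pts, tMs,
                        origin, voxelSize) {
  nt <- length(tt)
  if (coverage == "full") {
    tm <- tMs %% cycleMs
    f1 <- findInterval(tm, tt)
    f1[f1 < 1L] <- nt       # before the first trigger: wrap segment
    f2 <- f1 %% nt + 1L
    t1 <- tt[f1]
    dt <- tt[f2] - t1
    dt[f2 == 1L] <- cycleMs - t1[f2 == 1L] + tt[1]
    aRaw <- (tm - t1) %% cycleMs / dt
  } else {
    tm <- pmin(pmax(tMs, tt[1]), tt[nt])
    f1 <- pmin(findInterval(tm, tt), nt - 1L)
    f2 <- f1 + 1L
    aRaw <- (tm - tt[f1]) / (tt[f2] - tt[f1])
  }
  out <- matrix(NA_real_, nrow(pts), 3)
  ## tMs is scalar in the integrator, so f1/f2/a are scalar
  f1 <- f1[1]; f2 <- f2[1]; a <- aRaw[1]
  for (comp in 1:3) {
    v1 <- .trilinear(vlist[[f1]][[comp]], pts, origin, voxelSize)
    v2 <- .trilinear(vlist[[f2]][[comp]], pts, origin, voxelSize)
    out[, comp] <- (1 - a) * v1 + a * v2
  }
  out
}

#' Trace pathlines through a time-resolved velocity field
#'
#' Massless particles are advected by fixed-step 4th-order Runge-Kutta
#' integration of `x'(t) = v(x, t)`, with trilinear spatial and linear
#' temporal interpolation of the velocity (periodic in time for
#' full-coverage data; truncated data clamp to the last frame, with a
#' warning). Emitters release `particlesPerRelease` particles every
#' `releaseIntervalMs` from time 0 up to the end of the traced interval;
#' particles whose stencil leaves the sampled volume are frozen at their
#' last position and flagged. Fully deterministic given the inputs and
#' `seed` (used only to scatter particles inside emitter spheres of positive
#' radius).
#'
#' @param field a [VelocityField4D-class].
#' @param emitters list of [EmitterSpec-class] (emitters must lie inside the
#'   volume).
#' @param stepMs RK4 step, ms (default 1).
#' @param durationMs traced interval, ms; default one cardiac cycle.
#' @param outputEveryMs interval between stored positions (default 10 ms;
#'   rounded to a multiple of `stepMs`).
#' @param seed RNG seed for emitter-sphere sampling.
#' @return A [PathlineSet-class] (ungraded; see [gradeContainment()]).
#' @export
tracePathlines <- function(field, emitters, stepMs = 1,
                           durationMs = cycleMs(field),
                           outputEveryMs = 10, seed = 1L) {
  stopifnot(is(field, "VelocityField4D"), stepMs > 0)
  if (is(emitters, "EmitterSpec")) emitters <- list(emitters)
  d <- dim(field@velocity)
  upper <- field@origin + (d[1:3] - 1) * field@voxelSize
  for (em in emitters)
    if (any(em@position < field@origin) || any(em@position > upper))
      stop("geometry error: emitter outside the volume")
  if (field@coverage == "truncated")
    warning("truncated coverage: velocities clamped to the last frame ",
            "beyond the covered interval")

  ## release schedule
  posL <- list(); emId <- integer(0); relMs <- numeric(0)
  .withSeed(seed, {
    for (e in seq_along(emitters)) {
      em <- emitters[[e]]
      releases <- seq(0, durationMs, by = em@releaseIntervalMs)
      releases <- releases[releases < durationMs - 1e-9]
      for (rt in releases) {
        for (p in seq_len(em@particlesPerRelease)) {
          offset <- c(0, 0, 0)
          if (em@radiusMm > 0) {
            repeat {
              offset <- stats::runif(3, -1, 1)
              if (sum(offset^2) <= 1) break
            }
            offset <- offset * em@radiusMm
          }
          posL[[length(posL) + 1L]] <- em@position + offset
          emId <- c(emId, e)
          relMs <- c(relMs, rt)
        }
      }
    }
  })
  np <- length(posL)
  cur <- do.call(rbind, posL)
  alive <- rep(FALSE, np)     # released and still inside the volume
  frozen <- rep(FALSE, np)    # left the volume
  released <- rep(FALSE, np)

  nt <- dim(field@velocity)[4]
  vlist <- lapply(seq_len(nt), function(f)
    lapply(1:3, function(comp) field@velocity[, , , f, comp]))

  nSteps <- ceiling(durationMs / stepMs - 1e-9)
  outStride <- max(1L, round(outputEveryMs / stepMs))
  outSteps <- unique(c(seq(0L, nSteps, by = outStride), nSteps))
  outTimes <- outSteps * stepMs
  positions <- array(NA_real_, dim = c(np, 3L, length(outTimes)))

  evalV <- function(pts, tMs) {
    .velocityAt(vlist, field@triggerTimes, field@cycleMs, field@coverage,
                pts, rep(tMs, nrow(pts)), field@origin, field@voxelSize)
  }
  h <- stepMs
  outK <- 1L
  for (s in 0:nSteps) {
    tNow <- s * h
    newRel <- !released & relMs <= tNow + 1e-9
    if (any(newRel)) { released[newRel] <- TRUE; alive[newRel] <- TRUE }
    if (s %in% outSteps) {
      positions[released, , outK] <- cur[released, , drop = FALSE]
      outK <- outK + 1L
    }
    if (s == nSteps) break
    act <- which(alive)
    if (length(act)) {
      x <- cur[act, , drop = FALSE]
      k1 <- evalV(x, tNow)
      k2 <- evalV(x + h / 2000 * k1, tNow + h / 2)
      k3 <- evalV(x + h / 2000 * k2, tNow + h / 2)
      k4 <- evalV(x + h / 1000 * k3, tNow + h)
      dx <- h / 6000 * (k1 + 2 * k2 + 2 * k3 + k4)
      bad <- !is.finite(rowSums(dx))
      xNew <- x + dx
      xNew[bad, ] <- x[bad, , drop = FALSE]   # freeze at last valid position
      cur[act, ] <- xNew
      if (any(bad)) {
        frozen[act[bad]] <- TRUE
        alive[act[bad]] <- FALSE
      }
    }
  }
  new("PathlineSet", positions = positions, timesMs = outTimes,
      emitterId = emId, releaseMs = relMs, leftVolume = frozen,
      insidePool = matrix(logical(0), 0, 0),
      emitterLabels = vapply(emitters, function(e) e@label, character(1)),
      origin = field@origin, voxelSize = field@voxelSize,
      gridShape = d[1:3],
      emitterStats = data.frame(), meanScore = NA_real_)
}

#' Grade pathline blood-pool containment on a 0-3 scale
#'
#' For each emitter, the fraction of its particles ever sampled outside the
#' blood-pool mask (nearest-voxel lookup; leaving the sampled volume counts
#' as escaped) is converted to a quality grade: 0 (ideal, no escapes),
#' 1 (few), 2 (moderate), 3 (large amount). The verbal scale is
#' operationalised by configurable fraction thresholds — defaults: grade 1
#' for fractions in (0, 0.05], 2 in (0.05, 0.2], 3 above. The mean quality
#' score is the unweighted mean of the emitter grades. Once a particle is
#' flagged escaped it stays escaped.
#'
#' @param paths a [PathlineSet-class].
#' @param bloodPoolMask logical 3-D array on the source field's grid.
#' @param thresholds increasing length-2 numeric: upper fraction bounds for
#'   grades 1 and 2.
#' @return The [PathlineSet-class] with `insidePool`, per-emitter stats and
#'   `meanScore` filled; see [emitterGrades()] and [meanQualityScore()].
#' @export
gradeContainment <- function(paths, bloodPoolMask,
                             thresholds = c(0.05, 0.20)) {
  stopifnot(is(paths, "PathlineSet"))
  if (!any(bloodPoolMask)) stop("empty blood-pool mask")
  if (!all(dim(bloodPoolMask) == paths@gridShape))
    stop("mask geometry does not match the traced field")
  np <- dim(paths@positions)[1]
  ntOut <- dim(paths@positions)[3]
  inside <- matrix(NA, np, ntOut)
  maskNum <- array(as.numeric(bloodPoolMask), dim = dim(bloodPoolMask))
  for (k in seq_len(ntOut)) {
    act <- which(!is.na(paths@positions[, 1, k]))
    if (!length(act)) next
    val <- .nearest(maskNum, matrix(paths@positions[act, , k], ncol = 3L),
                    paths@origin, paths@voxelSize)
    inside[act, k] <- !is.na(val) & val > 0
  }
  escaped <- apply(inside, 1, function(r) any(!r[!is.na(r)])) |
    paths@leftVolume
  nem <- length(paths@emitterLabels)
  frac <- numeric(nem); grade <- integer(nem); counts <- integer(nem)
  for (e in seq_len(nem)) {
    sel <- paths@emitterId == e
    counts[e] <- sum(sel)
    frac[e] <- if (counts[e]) sum(escaped[sel]) / counts[e] else NA_real_
    grade[e] <- if (frac[e] == 0) 0L
      else if (frac[e] <= thresholds[1]) 1L
      else if (frac[e] <= thresholds[2]) 2L
      else 3L
  }
  out <- paths
  out@insidePool <- inside
  out@emitterStats <- data.frame(
    emitter_id = seq_len(nem) - 1L, label = paths@emitterLabels,
    n_particles = counts, fraction_escaped = frac, grade = grade)
  out@meanScore <- mean(grade)
  out
}
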