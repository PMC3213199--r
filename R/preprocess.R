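#' @include AllClasses.R phantom.R
NULL

#' Detect static tissue from temporal velocity variation
#'
#' Marks voxels whose speed varies little over the cardiac cycle and whose
#' signal magnitude indicates tissue (not air). Used to select voxels for the
#' eddy-current background fit. The mask is returned, never applied silently.
#'
#' @param field a [VelocityField4D-class] with at least 2 frames.
#' @param speedSdThreshold temporal standard deviation of speed below which a
#'   voxel counts as static, mm/s. Default 10% of VENC.
#' @param magnitudeThreshold minimum time-averaged magnitude for a voxel to
#'   count as tissue; default half the 99th percentile of the time-averaged
#'   magnitude (excludes air).
#' @return Logical 3-D array.
#' @export
detectStaticTissue <- function(field, speedSdThreshold = 0.1 * venc(field),
                               magnitudeThreshold = NULL) {
  stopifnot(is(field, "VelocityField4D"))
  d <- dim(field@velocity)
  nt <- d[4]
  nvox <- prod(d[1:3])
  sp2 <- matrix(0, nvox, nt)
  for (f in seq_len(nt)) {
    s <- 0
    for (comp in 1:3) s <- s + as.vector(field@velocity[, , , f, comp])^2
    sp2[, f] <- s
  }
  speed <- sqrt(sp2)
  mu <- rowMeans(speed)
  sdSpeed <- sqrt(pmax(rowSums((speed - mu)^2), 0) / (nt - 1))
  magMean <- 0
  for (f in seq_len(nt)) magMean <- magMean + as.vector(field@magnitude[, , , f])
  magMean <- magMean / nt
  if (is.null(magnitudeThreshold))
    magnitudeThreshold <- 0.5 * stats::quantile(magMean, 0.99, names = FALSE)
  mask <- sdSpeed < speedSdThreshold & magMean > magnitudeThreshold
  if (!any(mask))
    stop("correction error: no static tissue detected; supply a static mask")
  array(mask, dim = d[1:3])
}

#' Fit a first-order background-phase model to static tissue
#'
#' Least-squares fit of `c0 + c1 x + c2 y + c3 z` per velocity component to
#' the time-averaged velocity over static-tissue voxels. Eddy-current
#' offsets are modelled as stationary over the cycle, so a single fit to the
#' time average serves every frame.
#'
#' The fit is made robust to slow-moving blood leaking into the static mask
#' (slow near-wall flow is hard to distinguish from static tissue by
#' temporal variation alone): after an initial least-squares pass, voxels
#' whose residual exceeds 3x the residual RMS are discarded and the model is
#' refitted, twice.
#'
#' @param field a [VelocityField4D-class].
#' @param staticMask logical 3-D array (from [detectStaticTissue()] or
#'   supplied by the user); must contain at least 4 non-coplanar voxels.
#' @return A [BackgroundModel-class].
#' @export
fitBackground <- function(field, staticMask) {
  stopifnot(is(field, "VelocityField4D"))
  d <- dim(field@velocity)
  if (!all(dim(staticMask) == d[1:3]))
    stop("static mask geometry does not match the field")
  idx <- which(staticMask)
  if (length(idx) < 4L)
    stop("rank-deficiency error: need at least 4 static voxels")
  co <- .voxelCoords(d[1:3], field@voxelSize, field@origin)
  X <- cbind(1, co$x[idx], co$y[idx], co$z[idx])
  if (qr(X)$rank < 4L)
    stop("rank-deficiency error: static voxels are coplanar/degenerate")
  nt <- d[4]
  coefs <- matrix(0, 4L, 3L)
  rms <- numeric(3L)
  for (comp in 1:3) {
    y <- 0
    for (f in seq_len(nt)) y <- y + field@velocity[, , , f, comp][idx]
    y <- y / nt
    keep <- rep(TRUE, length(y))
    for (pass in 1:3) {
      fit <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])
      r <- fit$residuals
      rmsPass <- sqrt(mean(r^2))
      if (pass == 3L) break
      drop <- abs(r) > max(3 * rmsPass, 1e-9)
      if (!any(drop)) break
      cand <- keep
      cand[which(keep)[drop]] <- FALSE
      if (sum(cand) < 4L || qr(X[cand, , drop = FALSE])$rank < 4L) break
      keep <- cand
    }
    coefs[, comp] <- fit$coefficients
    rms[comp] <- sqrt(mean(fit$residuals^2))
  }
  new("BackgroundModel", coefficients = coefs, staticMask = staticMask,
      fitResidualRms = rms, nStatic = length(idx))
}

#' Evaluate a background model on a field's voxel grid
#'
#' @param model a [BackgroundModel-class].
#' @param field the [VelocityField4D-class] whose grid to evaluate on.
#' @return Array `nx x ny x nz x 3` of modelled offsets, mm/s.
#' @export
evaluateBackground <- function(model, field) {
  d <- dim(field@velocity)
  co <- .voxelCoords(d[1:3], field@voxelSize, field@origin)
  out <- array(0, dim = c(d[1:3], 3L))
  for (comp in 1:3) {
    cc <- model@coefficients[, comp]
    out[, , , comp] <- cc[1] + cc[2] * co$x + cc[3] * co$y + cc[4] * co$z
  }
  out
}

#' Subtract a fitted background-phase model from every frame
#'
#' The model is evaluated at each voxel centre and subtracted from all frames
#' of the matching velocity component. Exactly invertible: subtracting and
#' then adding the same model restores the input.
#'
#' @param field a [VelocityField4D-class].
#' @param model a [BackgroundModel-class].
#' @param add subtract (default) or add the model back.
#' @return The corrected [VelocityField4D-class].
#' @export
correctBackground <- function(field, model, add = FALSE) {
  stopifnot(is(field, "VelocityField4D"), is(model, "BackgroundModel"))
  bg <- evaluateBackground(model, field)
  sgn <- if (add) 1 else -1
  out <- field
  nt <- nFrames(field)
  for (comp in 1:3)
    for (f in seq_len(nt))
      out@velocity[, , , f, comp] <-
        out@velocity[, , , f, comp] + sgn * bg[, , , comp]
  out
}

## round() with exact-half ties broken toward zero (the smaller correction)
.roundTieSmall <- function(x) {
  r <- round(x)
  f <- x - floor(x)
  tie <- f == 0.5
  r[tie] <- trunc(x[tie])
  r
}

#' Temporal phase-unwrapping of aliased velocities
#'
#' Velocities beyond +/-VENC alias by multiples of 2*VENC. Each voxel's
#' component time series is unwrapped independently in time: scanning frames
#' in cyclic order starting from the frame of minimum absolute velocity
#' (assumed alias-free — flow is near zero in diastole), each next sample is
#' shifted by the multiple of 2*VENC that minimises the frame-to-frame jump.
#' A jump of exactly VENC is ambiguous and resolved toward the smaller
#' correction; such samples are counted and reported. Idempotent on data with
#' no remaining jumps above VENC.
#'
#' @param field a [VelocityField4D-class].
#' @return The unwrapped field (stage `"unwrapped"`), with attributes
#'   `nUnwrapped` (samples shifted) and `nAmbiguous` (exact-VENC jumps)
#'   recorded in the slot-free attribute list returned by
#'   [unwrapReport()].
#' @export
unwrapVelocity <- function(field) {
  stopifnot(is(field, "VelocityField4D"))
  d <- dim(field@velocity)
  nt <- d[4]
  twoV <- 2 * field@venc
  nUn <- 0L
  nAmb <- 0L
  out <- field
  for (comp in 1:3) {
    M <- matrix(field@velocity[, , , , comp], ncol = nt)
    start <- max.col(-abs(M), ties.method = "first")
    rows <- seq_len(nrow(M))
    ## rotate each row so its start frame is column 1
    R <- matrix(0, nrow(M), nt)
    colIdx <- matrix(0L, nrow(M), nt)
    for (j in seq_len(nt)) {
      cj <- ((start + j - 2L) %% nt) + 1L
      colIdx[, j] <- cj
      R[, j] <- M[cbind(rows, cj)]
    }
    prev <- R[, 1]
    for (j in 2:nt) {
      k0 <- (prev - R[, j]) / twoV
      m <- .roundTieSmall(k0)
      nAmb <- nAmb + sum(abs(k0 - trunc(k0)) == 0.5)
      nUn <- nUn + sum(m != 0)
      R[, j] <- R[, j] + m * twoV
      prev <- R[, j]
    }
    for (j in seq_len(nt)) M[cbind(rows, colIdx[, j])] <- R[, j]
    out@velocity[, , , , comp] <- array(M, dim = d[1:4])
  }
  out@stage <- "unwrapped"
  attr(out, "nUnwrapped") <- nUn
  attr(out, "nAmbiguous") <- nAmb
  out
}

#' Report counts from the last unwrap of a field
#'
#' @param field a field returned by [unwrapVelocity()].
#' @return List with `nUnwrapped` and `nAmbiguous` sample counts.
#' @export
unwrapReport <- function(field) {
  list(nUnwrapped = attr(field, "nUnwrapped"),
       nAmbiguous = attr(field, "nAmbiguous"))
}
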