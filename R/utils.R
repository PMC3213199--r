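## Internal numerical helpers: phase wrap, cyclic integration, trilinear
## sampling, polygon geometry, rectilinear region boundary tracing.

#' Wrap velocities into the VENC range
#'
#' Applies the phase-wrap map of velocity-encoded MRI: values outside
#' (-venc, venc] are shifted by multiples of 2*venc until in range, as an
#' acquisition would alias them.
#'
#' @param v numeric vector/array, mm/s.
#' @param venc velocity-encoding limit, mm/s.
#' @return Wrapped values in (-venc, venc], same shape as `v`.
#' @examples
#' wrapToVenc(1000, 800)   # -600
#' @export
wrapToVenc <- function(v, venc) {
  stopifnot(venc > 0)
  w <- ((v + venc) %% (2 * venc)) - venc
  ## map the -venc boundary to +venc so the range is (-venc, venc]
  w[w == -venc & v > 0] <- venc
  w
}

## Cyclic trapezoidal integral of y(t) over one cycle [0, cycleMs), in
## (units of y) * s.  Closes the curve from the last sample back to the
## first across the period wrap.
.cyclicTrapz <- function(timesMs, y, cycleMs) {
  n <- length(y)
  dt <- diff(timesMs)
  s <- sum(dt * (y[-n] + y[-1])) / 2
  s <- s + (cycleMs - timesMs[n] + timesMs[1]) * (y[n] + y[1]) / 2
  s / 1000
}

## Open trapezoid over the covered support [t1, coveredMs): trapezoid across
## samples plus a zero-order hold from the last frame to the coverage end.
.truncatedTrapz <- function(timesMs, y, coveredMs) {
  n <- length(y)
  dt <- diff(timesMs)
  s <- sum(dt * (y[-n] + y[-1])) / 2
  s <- s + (coveredMs - timesMs[n]) * y[n]
  s / 1000
}

## Trilinear sampling of a 3-D array at world points.
## pts: m x 3 matrix (mm). Returns length-m values, NA outside the volume.
.trilinear <- function(vol, pts, origin, voxelSize) {
  d <- dim(vol)
  g <- sweep(sweep(pts, 2, origin, "-"), 2, voxelSize, "/") + 1
  i0 <- floor(g)
  ## points exactly on the upper face belong to the last cell
  for (k in 1:3) i0[g[, k] == d[k], k] <- d[k] - 1
  fr <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE   # non-finite input points
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  lin <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) - 1) + d[1] * d[2] * ((i0[, 3] + dz) - 1)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  out[ok] <-
    vol[lin(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[lin(1, 0, 0)] * fx       * (1 - fy) * (1 - fz) +
    vol[lin(0, 1, 0)] * (1 - fx) * fy       * (1 - fz) +
    vol[lin(1, 1, 0)] * fx       * fy       * (1 - fz) +
    vol[lin(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
    vol[lin(1, 0, 1)] * fx       * (1 - fy) * fz +
    vol[lin(0, 1, 1)] * (1 - fx) * fy       * fz +
    vol[lin(1, 1, 1)] * fx       * fy       * fz
  out
}

## Nearest-neighbour sampling, same contract as .trilinear.
.nearest <- function(vol, pts, origin, voxelSize) {
  d <- dim(vol)
  g <- round(sweep(sweep(pts, 2, origin, "-"), 2, voxelSize, "/") + 1)
  ok <- g[, 1] >= 1 & g[, 1] <= d[1] &
        g[, 2] >= 1 & g[, 2] <= d[2] &
        g[, 3] >= 1 & g[, 3] <= d[3]
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    gi <- g[ok, , drop = FALSE]
    out[ok] <- vol[gi[, 1] + d[1] * (gi[, 2] - 1) + d[1] * d[2] * (gi[, 3] - 1)]
  }
  out
}

## Shoelace signed area (mm^2); positive for counter-clockwise vertices.
.polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## Proper-crossing test for polygon simplicity (shared endpoints between
## adjacent edges allowed). O(n^2), adequate for contour sizes here.
.polygonIsSimple <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip adjacent (wrapping) edge pair
    if (!length(js)) next
    d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                 rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross2(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                 rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## Even-odd point-in-polygon, vectorised over points; points exactly on an
## edge count as inside (deterministic tie rule).
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  eps <- 1e-12
  for (e in seq_len(n)) {
    x1 <- x[e]; y1 <- y[e]; x2 <- xn[e]; y2 <- yn[e]
    ## on-edge check
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg <- d <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onEdge <- onEdge | seg
    ## ray casting (horizontal ray to +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xi
      inside <- xor(inside, hit)
    }
  }
  inside | onEdge
}

## Trace the outer boundary of a pixel region (logical nu x nv matrix) as a
## counter-clockwise rectilinear polygon through pixel corners.
## centersU/centersV: pixel-centre coordinates (mm); h: pixel size.
## Pixel centres strictly inside the returned polygon reproduce the region
## (up to interior holes, which threshold-grown regions do not have).
.traceRegionBoundary <- function(region, centersU, centersV, h) {
  nu <- nrow(region); nv <- ncol(region)
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region")
  ## corner lattice: corner (i, j), i in 0..nu, j in 0..nv at
  ## (centersU[1] + (i - 0.5) h, centersV[1] + (j - 0.5) h) relative to pixel 1
  cid <- function(i, j) i + (nu + 1L) * j + 1L
  inReg <- function(i, j) i >= 1L & i <= nu & j >= 1L & j <= nv &
    region[cbind(pmax(pmin(i, nu), 1L), pmax(pmin(j, nv), 1L))]
  from <- integer(0); to <- integer(0)
  i <- idx[, 1]; j <- idx[, 2]
  ## CCW boundary edges (interior on the left of travel direction)
  b <- !inReg(i, j - 1L)   # bottom: corner(i-1, j-1) -> (i, j-1)
  from <- c(from, cid(i[b] - 1L, j[b] - 1L)); to <- c(to, cid(i[b], j[b] - 1L))
  r <- !inReg(i + 1L, j)   # right: (i, j-1) -> (i, j)
  from <- c(from, cid(i[r], j[r] - 1L)); to <- c(to, cid(i[r], j[r]))
  tp <- !inReg(i, j + 1L)  # top: (i, j) -> (i-1, j)
  from <- c(from, cid(i[tp], j[tp])); to <- c(to, cid(i[tp] - 1L, j[tp]))
  l <- !inReg(i - 1L, j)   # left: (i-1, j) -> (i-1, j-1)
  from <- c(from, cid(i[l] - 1L, j[l])); to <- c(to, cid(i[l] - 1L, j[l] - 1L))
  ## chain directed edges into loops; keep the loop of largest |area|
  nxt <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  bestLoop <- NULL; bestArea <- -1
  for (startE in seq_along(from)) {
    if (used[startE]) next
    loop <- integer(0)
    e <- startE
    repeat {
      used[e] <- TRUE
      loop <- c(loop, from[e])
      cands <- nxt[[as.character(to[e])]]
      cands <- cands[!used[cands]]
      if (!length(cands)) break
      e <- cands[1]
    }
    cu <- (loop - 1L) %% (nu + 1L)
    cv <- (loop - 1L) %/% (nu + 1L)
    pu <- centersU[1] + (cu - 0.5) * h
    pv <- centersV[1] + (cv - 0.5) * h
    poly <- cbind(pu, pv)
    ar <- abs(.polygonArea(poly))
    if (ar > bestArea) { bestArea <- ar; bestLoop <- poly }
  }
  ## drop collinear runs (rectilinear: keep only direction changes)
  p <- bestLoop
  n <- nrow(p)
  keep <- logical(n)
  for (k in seq_len(n)) {
    prev <- p[if (k == 1) n else k - 1, ]
    nxtv <- p[if (k == n) 1 else k + 1, ]
    d1 <- p[k, ] - prev
    d2 <- nxtv - p[k, ]
    keep[k] <- abs(d1[1] * d2[2] - d1[2] * d2[1]) > 1e-12
  }
  p <- p[keep, , drop = FALSE]
  colnames(p) <- c("u_mm", "v_mm")
  p
}

## Evaluate the spec-determined seed without disturbing the caller's RNG
## stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
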