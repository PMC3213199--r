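#' @include AllClasses.R utils.R
NULL

#' Construct an oriented sampled plane
#'
#' If `uAxis`/`vAxis` are not given, an orthonormal in-plane basis is built
#' from the normal (deterministically: the world axis least aligned with the
#' normal is projected into the plane and normalised). Supplied axes are
#' re-orthonormalised by Gram-Schmidt so the triad meets the 1e-12 validity
#' tolerance, and `vAxis` is chosen so that `uAxis x vAxis = normal`
#' (right-handed).
#'
#' @param origin plane centre, mm.
#' @param normal plane normal (normalised internally).
#' @param uAxis,vAxis optional in-plane axes.
#' @param pixelSize pixel spacing, mm.
#' @param extent pixels `(nu, nv)`.
#' @return A [PlaneDefinition-class].
#' @examples
#' planeDefinition(c(0, 0, 0), normal = c(0, 0.3, 1), pixelSize = 1,
#'                 extent = c(40, 40))
#' @export
planeDefinition <- function(origin, normal, uAxis = NULL, vAxis = NULL,
                            pixelSize, extent) {
  n <- normal / sqrt(sum(normal^2))
  if (is.null(uAxis)) {
    seed <- diag(3)[, which.min(abs(n))]
    u <- seed - sum(seed * n) * n
    u <- u / sqrt(sum(u^2))
  } else {
    u <- uAxis - sum(uAxis * n) * n
    u <- u / sqrt(sum(u^2))
  }
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])   # n x u, so that u x v = n
  if (!is.null(vAxis) && sum(v * vAxis) < 0)
    stop("supplied vAxis makes a left-handed triad with uAxis and normal")
  new("PlaneDefinition", origin = as.numeric(origin), normal = as.numeric(n),
      uAxis = as.numeric(u), vAxis = as.numeric(v),
      pixelSize = as.numeric(pixelSize), extent = as.integer(extent))
}

## Pixel-centre world positions of a plane, as an (nu*nv) x 3 matrix in
## column-major pixel order, plus the plane-local (u, v) coordinates.
.planePixelPositions <- function(plane) {
  nu <- plane@extent[1]; nv <- plane@extent[2]
  h <- plane@pixelSize
  us <- (seq_len(nu) - (nu + 1) / 2) * h
  vs <- (seq_len(nv) - (nv + 1) / 2) * h
  U <- rep(us, times = nv)
  V <- rep(vs, each = nu)
  P <- matrix(plane@origin, nrow = nu * nv, ncol = 3, byrow = TRUE) +
    outer(U, plane@uAxis) + outer(V, plane@vAxis)
  list(P = P, u = us, v = vs)
}

#' Reformat a 4D dataset onto an arbitrary 2D plane
#'
#' For every frame and plane pixel, the three Cartesian velocity components
#' are interpolated at the pixel's 3D position and projected onto the plane
#' normal, giving the through-plane velocity `v . n`; the magnitude is
#' interpolated the same way. Pixels outside the volume are flagged invalid
#' (`NA`), never zero-filled. Trilinear interpolation (the default) is exact
#' for affine velocity fields; nearest-neighbour is available for
#' sensitivity checks.
#'
#' @param field a [VelocityField4D-class].
#' @param plane a [PlaneDefinition-class]; must intersect the volume.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [Series2D-class].
#' @export
reformatPlane <- function(field, plane,
                          interpolation = c("trilinear", "nearest")) {
  stopifnot(is(field, "VelocityField4D"), is(plane, "PlaneDefinition"))
  interpolation <- match.arg(interpolation)
  sampler <- if (interpolation == "trilinear") .trilinear else .nearest
  pp <- .planePixelPositions(plane)
  nu <- plane@extent[1]; nv <- plane@extent[2]
  nt <- nFrames(field)
  ## validity is purely geometric: test with one (any) volume
  probe <- sampler(field@magnitude[, , , 1], pp$P, field@origin,
                   field@voxelSize)
  valid <- matrix(!is.na(probe), nu, nv)
  if (!any(valid))
    stop("geometry error: plane lies fully outside the volume")
  n <- plane@normal
  vth <- array(NA_real_, dim = c(nu, nv, nt))
  mag <- array(NA_real_, dim = c(nu, nv, nt))
  for (f in seq_len(nt)) {
    acc <- 0
    for (comp in 1:3) {
      s <- sampler(field@velocity[, , , f, comp], pp$P, field@origin,
                   field@voxelSize)
      acc <- acc + n[comp] * s
    }
    vth[, , f] <- matrix(acc, nu, nv)
    mag[, , f] <- matrix(sampler(field@magnitude[, , , f], pp$P,
                                 field@origin, field@voxelSize), nu, nv)
  }
  new("Series2D", vThrough = vth, magnitude = mag, valid = valid,
      plane = plane, pixelSize = plane@pixelSize,
      triggerTimes = field@triggerTimes, cycleMs = field@cycleMs,
      coveredMs = field@coveredMs, venc = field@venc,
      coverage = field@coverage)
}
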