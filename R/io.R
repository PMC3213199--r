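#' @include AllClasses.R phantom.R
NULL

## On-disk layout of a VelocityField4D (directory):
##   velocity_x.nii, velocity_y.nii, velocity_z.nii, magnitude.nii  (4D, float64)
##   meta.json  (geometry, timing, venc, coverage, stage, convention)
## Coordinate convention, stated in every metadata file: right-handed,
## millimetres, voxel centre of 0-based index (i,j,k) at
## origin + (i,j,k) * voxel_size; time in ms from the R-wave.

.convention <- paste(
  "right-handed mm; voxel center at origin + index*voxel_size (0-based);",
  "time in ms from R-wave; velocity in mm/s along x,y,z")

.writeJson <- function(x, path) {
  ## 17 significant digits: doubles round-trip bit-exactly through decimal
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
}

.writeVolume <- function(arr, path, voxelSize) {
  pd <- c(-1, voxelSize, rep(1, 4))[1:8]   # qfac + spatial + time/extra dims
  img <- RNifti::asNifti(arr, reference = list(pixdim = pd),
                         datatype = "double", internal = FALSE)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

.readVolume <- function(path) {
  if (!file.exists(path))
    stop("format error: missing component file '", basename(path), "'")
  arr <- RNifti::readNifti(path)
  a <- array(as.numeric(arr), dim = dim(arr))
  a
}

#' Write a 4D velocity dataset to a directory
#'
#' Writes one float64 NIfTI volume per velocity component plus the magnitude
#' (4D: x, y, z, t) and a `meta.json` with the full geometry, timing, VENC,
#' coverage and processing-stage metadata and the coordinate convention.
#' [readDataset()] is its exact inverse.
#'
#' @param field a [VelocityField4D-class].
#' @param path output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeDataset <- function(field, path) {
  stopifnot(is(field, "VelocityField4D"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  comp <- c("x", "y", "z")
  for (k in 1:3)
    .writeVolume(field@velocity[, , , , k],
                 file.path(path, paste0("velocity_", comp[k], ".nii")),
                 field@voxelSize)
  .writeVolume(field@magnitude, file.path(path, "magnitude.nii"),
               field@voxelSize)
  meta <- list(
    voxel_size_mm = field@voxelSize,
    origin_mm = field@origin,
    trigger_times_ms = field@triggerTimes,
    cycle_ms = field@cycleMs,
    covered_ms = field@coveredMs,
    venc_mm_s = field@venc,
    coverage_flag = field@coverage,
    processing_stage = field@stage,
    coordinate_convention = .convention
  )
  .writeJson(meta, file.path(path, "meta.json"))
  invisible(path)
}

#' Read a 4D velocity dataset written by [writeDataset()]
#'
#' Validates geometry while reading: missing component files, inconsistent
#' array shapes, missing VENC and non-increasing trigger times are rejected
#' with an error naming the offending file or field, never silently
#' reinterpreted.
#'
#' @param path dataset directory.
#' @return A [VelocityField4D-class].
#' @export
readDataset <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath))
    stop("format error: missing component file 'meta.json'")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (fld in c("venc_mm_s", "voxel_size_mm", "origin_mm",
                "trigger_times_ms", "cycle_ms"))
    if (is.null(meta[[fld]]))
      stop("format error: 'meta.json' lacks required field '", fld, "'")
  comp <- c("x", "y", "z")
  vols <- lapply(comp, function(cc)
    .readVolume(file.path(path, paste0("velocity_", cc, ".nii"))))
  mag <- .readVolume(file.path(path, "magnitude.nii"))
  d <- dim(vols[[1]])
  for (k in 2:3)
    if (!identical(dim(vols[[k]]), d))
      stop("format error: inconsistent shapes in 'velocity_",
           comp[k], ".nii'")
  if (!identical(dim(mag), d))
    stop("format error: inconsistent shapes in 'magnitude.nii'")
  vel <- array(0, dim = c(d, 3L))
  for (k in 1:3) vel[, , , , k] <- vols[[k]]
  velocityField4D(
    vel, mag,
    voxelSize = meta$voxel_size_mm, origin = meta$origin_mm,
    triggerTimes = meta$trigger_times_ms, cycleMs = meta$cycle_ms,
    venc = meta$venc_mm_s,
    coverage = if (is.null(meta$coverage_flag)) "full" else meta$coverage_flag,
    coveredMs = if (is.null(meta$covered_ms)) meta$cycle_ms else meta$covered_ms,
    stage = if (is.null(meta$processing_stage)) "wrapped"
            else meta$processing_stage)
}

#' Write / read a logical mask volume
#'
#' @param mask logical 3-D array.
#' @param path NIfTI file path.
#' @param voxelSize mm.
#' @return `writeMask` the path invisibly; `readMask` a logical array.
#' @export
writeMask <- function(mask, path, voxelSize = c(1, 1, 1)) {
  .writeVolume(array(as.numeric(mask), dim = dim(mask)), path, voxelSize)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  arr <- .readVolume(path)
  array(arr != 0, dim = dim(arr))
}

#' Write / read a reformatted 2D series
#'
#' The series is stored as `vthrough.nii` and `magnitude.nii` (nu x nv x nt,
#' invalid pixels as NaN), a `valid.nii` mask, and `series.json` holding the
#' plane definition, timing and VENC. Round-trips exactly.
#'
#' @param series a [Series2D-class].
#' @param path output directory.
#' @return The path, invisibly.
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "Series2D"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ps <- series@pixelSize
  vs <- c(ps, ps, 1)
  .writeVolume(series@vThrough, file.path(path, "vthrough.nii"), vs)
  .writeVolume(series@magnitude, file.path(path, "magnitude.nii"), vs)
  .writeVolume(array(as.numeric(series@valid), dim = c(dim(series@valid), 1L)),
               file.path(path, "valid.nii"), vs)
  pl <- series@plane
  meta <- list(
    plane = list(origin_mm = pl@origin, normal = pl@normal,
                 u_axis = pl@uAxis, v_axis = pl@vAxis,
                 pixel_size_mm = pl@pixelSize, extent_px = pl@extent),
    pixel_size_mm = series@pixelSize,
    trigger_times_ms = series@triggerTimes,
    cycle_ms = series@cycleMs,
    covered_ms = series@coveredMs,
    venc_mm_s = series@venc,
    coverage_flag = series@coverage,
    coordinate_convention = .convention
  )
  .writeJson(meta, file.path(path, "series.json"))
  invisible(path)
}

#' @rdname writeSeries
#' @export
readSeries <- function(path) {
  metaPath <- file.path(path, "series.json")
  if (!file.exists(metaPath))
    stop("format error: missing component file 'series.json'")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$venc_mm_s))
    stop("format error: 'series.json' lacks required field 'venc_mm_s'")
  v <- .readVolume(file.path(path, "vthrough.nii"))
  m <- .readVolume(file.path(path, "magnitude.nii"))
  val <- .readVolume(file.path(path, "valid.nii"))
  if (length(dim(val)) == 2L) val <- array(val, dim = c(dim(val), 1L))
  pl <- meta$plane
  plane <- planeDefinition(origin = pl$origin_mm, normal = pl$normal,
                           uAxis = pl$u_axis, vAxis = pl$v_axis,
                           pixelSize = pl$pixel_size_mm,
                           extent = pl$extent_px)
  new("Series2D", vThrough = v, magnitude = m,
      valid = matrix(val[, , 1] != 0, nrow = dim(val)[1]),
      plane = plane, pixelSize = meta$pixel_size_mm,
      triggerTimes = meta$trigger_times_ms, cycleMs = meta$cycle_ms,
      coveredMs = meta$covered_ms, venc = meta$venc_mm_s,
      coverage = meta$coverage_flag)
}

#' Write / read a flow curve
#'
#' CSV with columns `time_ms, flow_ml_s` plus a JSON sidecar
#' (`<stem>.json`) holding stroke volume, peak flow, cycle length and the
#' coverage flag.
#'
#' @param curve a [FlowCurve-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeFlowCurve <- function(curve, path) {
  stopifnot(is(curve, "FlowCurve"))
  df <- data.frame(time_ms = curve@timeMs, flow_ml_s = curve@flowMlS)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  .writeJson(list(stroke_volume_ml = curve@strokeVolumeMl,
                  peak_flow_ml_s = curve@peakFlowMlS,
                  cycle_ms = curve@cycleMs,
                  covered_ms = curve@coveredMs,
                  coverage_flag = curve@coverage), side)
  invisible(path)
}

#' @rdname writeFlowCurve
#' @export
readFlowCurve <- function(path) {
  df <- utils::read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("FlowCurve", timeMs = df$time_ms, flowMlS = df$flow_ml_s,
      strokeVolumeMl = meta$stroke_volume_ml,
      peakFlowMlS = meta$peak_flow_ml_s,
      coverage = meta$coverage_flag, coveredMs = meta$covered_ms,
      cycleMs = meta$cycle_ms)
}

#' Write / read a vessel contour
#'
#' CSV with columns `frame, vertex_index, u_mm, v_mm` (frame 0 denotes a
#' static contour used for all frames).
#'
#' @param contour a [VesselContour-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeContour <- function(contour, path) {
  stopifnot(is(contour, "VesselContour"))
  static <- length(contour@frames) == 1L
  rows <- do.call(rbind, lapply(seq_along(contour@frames), function(f) {
    p <- contour@frames[[f]]
    data.frame(frame = if (static) 0L else f,
               vertex_index = seq_len(nrow(p)) - 1L,
               u_mm = p[, 1], v_mm = p[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContour
#' @param label vessel label to attach on read.
#' @export
readContour <- function(path, label = "other") {
  df <- utils::read.csv(path)
  frames <- lapply(split(df, df$frame), function(d) {
    d <- d[order(d$vertex_index), ]
    cbind(u_mm = d$u_mm, v_mm = d$v_mm)
  })
  new("VesselContour", frames = unname(frames), label = label)
}

#' Write traced pathlines to CSV
#'
#' Columns `particle_id, emitter_id, time_ms, x, y, z, inside_pool`
#' (inside_pool is NA when the set has not been graded).
#'
#' @param paths a [PathlineSet-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writePathlines <- function(paths, path) {
  stopifnot(is(paths, "PathlineSet"))
  np <- dim(paths@positions)[1]
  nt <- dim(paths@positions)[3]
  graded <- ncol(paths@insidePool) == nt
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    act <- which(!is.na(paths@positions[p, 1, ]))
    if (!length(act)) next
    rows[[p]] <- data.frame(
      particle_id = p - 1L, emitter_id = paths@emitterId[p] - 1L,
      time_ms = paths@timesMs[act],
      x = paths@positions[p, 1, act],
      y = paths@positions[p, 2, act],
      z = paths@positions[p, 3, act],
      inside_pool = if (graded) paths@insidePool[p, act] else NA)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a plane definition to JSON (bit-exact round trip)
#'
#' @param plane a [PlaneDefinition-class].
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
writePlane <- function(plane, path) {
  stopifnot(is(plane, "PlaneDefinition"))
  .writeJson(list(origin_mm = plane@origin, normal = plane@normal,
                  u_axis = plane@uAxis, v_axis = plane@vAxis,
                  pixel_size_mm = plane@pixelSize,
                  extent_px = plane@extent), path)
  invisible(path)
}

#' @rdname writePlane
#' @export
readPlane <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  planeDefinition(origin = m$origin_mm, normal = m$normal,
                  uAxis = m$u_axis, vAxis = m$v_axis,
                  pixelSize = m$pixel_size_mm, extent = m$extent_px)
}
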