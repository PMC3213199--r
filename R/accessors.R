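#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("velocities", "VelocityField4D", function(object) object@velocity)

#' @rdname accessors
#' @export
setMethod("magnitudes", "VelocityField4D", function(object) object@magnitude)

#' @rdname accessors
#' @export
setMethod("magnitudes", "Series2D", function(object) object@magnitude)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VelocityField4D", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "VelocityField4D", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("triggerTimes", "VelocityField4D", function(object) object@triggerTimes)

#' @rdname accessors
#' @export
setMethod("triggerTimes", "Series2D", function(object) object@triggerTimes)

#' @rdname accessors
#' @export
setMethod("triggerTimes", "FlowCurve", function(object) object@timeMs)

#' @rdname accessors
#' @export
setMethod("cycleMs", "VelocityField4D", function(object) object@cycleMs)

#' @rdname accessors
#' @export
setMethod("cycleMs", "Series2D", function(object) object@cycleMs)

#' @rdname accessors
#' @export
setMethod("cycleMs", "FlowCurve", function(object) object@cycleMs)

#' @rdname accessors
#' @export
setMethod("coveredMs", "VelocityField4D", function(object) object@coveredMs)

#' @rdname accessors
#' @export
setMethod("coveredMs", "Series2D", function(object) object@coveredMs)

#' @rdname accessors
#' @export
setMethod("venc", "VelocityField4D", function(object) object@venc)

#' @rdname accessors
#' @export
setMethod("venc", "Series2D", function(object) object@venc)

#' @rdname accessors
#' @export
setMethod("coverage", "VelocityField4D", function(object) object@coverage)

#' @rdname accessors
#' @export
setMethod("coverage", "Series2D", function(object) object@coverage)

#' @rdname accessors
#' @export
setMethod("coverage", "FlowCurve", function(object) object@coverage)

#' @rdname accessors
#' @export
setMethod("processingStage", "VelocityField4D", function(object) object@stage)

#' @rdname accessors
#' @export
setMethod("nFrames", "VelocityField4D", function(object) dim(object@velocity)[4])

#' @rdname accessors
#' @export
setMethod("nFrames", "Series2D", function(object) dim(object@vThrough)[3])

#' @rdname accessors
#' @export
setMethod("strokeVolume", "FlowCurve", function(object) object@strokeVolumeMl)

#' @rdname accessors
#' @export
setMethod("strokeVolume", "GroundTruth", function(object) object@strokeVolumeMl)

#' @rdname accessors
#' @export
setMethod("peakFlow", "FlowCurve", function(object) object@peakFlowMlS)

#' @rdname accessors
#' @export
setMethod("peakFlow", "GroundTruth", function(object) object@peakFlowMlS)

#' @rdname accessors
#' @export
setMethod("flowValues", "FlowCurve", function(object) object@flowMlS)

#' @rdname accessors
#' @export
setMethod("flowValues", "GroundTruth", function(object) object@flowMlS)

#' @rdname accessors
#' @export
setMethod("throughPlaneVelocity", "Series2D", function(object) object@vThrough)

#' @rdname accessors
#' @export
setMethod("validPixels", "Series2D", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("planeOf", "Series2D", function(object) object@plane)

#' @rdname accessors
#' @export
setMethod("emitterGrades", "PathlineSet", function(object) {
  if (nrow(object@emitterStats) == 0L)
    stop("pathlines have not been graded; run gradeContainment() first")
  stats::setNames(object@emitterStats$grade, object@emitterStats$label)
})

#' @rdname accessors
#' @export
setMethod("meanQualityScore", "PathlineSet", function(object) {
  if (nrow(object@emitterStats) == 0L)
    stop("pathlines have not been graded; run gradeContainment() first")
  object@meanScore
})

setMethod("show", "VelocityField4D", function(object) {
  d <- dim(object@velocity)
  cat("VelocityField4D:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames\n")
  cat("  voxel size:", paste(format(object@voxelSize), collapse = " x "),
      "mm; cycle:", object@cycleMs, "ms; VENC:", object@venc, "mm/s\n")
  cat("  coverage:", object@coverage,
      sprintf("(%.0f/%.0f ms);", object@coveredMs, object@cycleMs),
      "stage:", object@stage, "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: tube radius", object@radius, "mm,",
      paste(object@gridShape, collapse = " x "), "grid at",
      paste(format(object@voxelSize), collapse = " x "), "mm\n")
  cat("  ", object@nFrames, " frames / ", object@cycleMs, " ms cycle; VENC ",
      object@venc, " mm/s; noise SD ", object@noiseSd, " mm/s; seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "Series2D", function(object) {
  d <- dim(object@vThrough)
  cat("Series2D:", d[1], "x", d[2], "pixels at", object@pixelSize, "mm,",
      d[3], "frames;", sum(object@valid), "valid pixels\n")
})

setMethod("show", "FlowCurve", function(object) {
  cat("FlowCurve:", length(object@flowMlS), "frames;",
      sprintf("SV %.2f ml; peak %.1f ml/s; coverage %s\n",
              object@strokeVolumeMl, object@peakFlowMlS, object@coverage))
})

setMethod("show", "PathlineSet", function(object) {
  cat("PathlineSet:", dim(object@positions)[1], "particles from",
      length(object@emitterLabels), "emitters,",
      length(object@timesMs), "output times\n")
  if (nrow(object@emitterStats) > 0L)
    cat(sprintf("  graded: mean quality score %.2f\n", object@meanScore))
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel (first-order), fitted on", object@nStatic,
      "static voxels\n")
  co <- object@coefficients
  rownames(co) <- c("intercept", "x", "y", "z")
  colnames(co) <- c("vx", "vy", "vz")
  print(signif(co, 4))
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport on", object@n, "pairs\n")
  cat(sprintf("  regression: slope %.4f, intercept %.4f, r^2 %.4f\n",
              object@slope, object@intercept, object@rSquared))
  cat(sprintf("  bias (%s denominator): %.2f +/- %.2f %%\n",
              object@denominator, object@biasPercentMean, object@biasPercentSd))
  cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.4g (%s)\n",
              object@wilcoxonStatistic, object@wilcoxonP,
              if (object@wilcoxonExact) "exact" else "normal approx."))
})
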