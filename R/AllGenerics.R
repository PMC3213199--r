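#' @include AllClasses.R
NULL

#' Accessors for pc4dflow objects
#'
#' Small generic accessors shared by the data containers: velocity and
#' magnitude arrays, grid geometry, timing, VENC, coverage and processing
#' stage, stroke volume and peak flow.
#'
#' @param object a pc4dflow object.
#' @return The slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))

#' @rdname accessors
#' @export
setGeneric("magnitudes", function(object) standardGeneric("magnitudes"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("triggerTimes", function(object) standardGeneric("triggerTimes"))

#' @rdname accessors
#' @export
setGeneric("cycleMs", function(object) standardGeneric("cycleMs"))

#' @rdname accessors
#' @export
setGeneric("coveredMs", function(object) standardGeneric("coveredMs"))

#' @rdname accessors
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("processingStage", function(object) standardGeneric("processingStage"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("strokeVolume", function(object) standardGeneric("strokeVolume"))

#' @rdname accessors
#' @export
setGeneric("peakFlow", function(object) standardGeneric("peakFlow"))

#' @rdname accessors
#' @export
setGeneric("flowValues", function(object) standardGeneric("flowValues"))

#' @rdname accessors
#' @export
setGeneric("throughPlaneVelocity", function(object)
  standardGeneric("throughPlaneVelocity"))

#' @rdname accessors
#' @export
setGeneric("validPixels", function(object) standardGeneric("validPixels"))

#' @rdname accessors
#' @export
setGeneric("planeOf", function(object) standardGeneric("planeOf"))

#' @rdname accessors
#' @export
setGeneric("emitterGrades", function(object) standardGeneric("emitterGrades"))

#' @rdname accessors
#' @export
setGeneric("meanQualityScore", function(object)
  standardGeneric("meanQualityScore"))
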