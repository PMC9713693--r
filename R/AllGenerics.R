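#' @rdname TraceSet-class
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname TraceSet-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname TraceSet-class
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname TraceSet-class
#' @export
setGeneric("roiCentroids", function(x) standardGeneric("roiCentroids"))

#' @rdname BandPowerSet-class
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname BandPowerSet-class
#' @export
setGeneric("bandPower", function(x, band) standardGeneric("bandPower"))

#' @rdname BandPowerSet-class
#' @export
setGeneric("validFrames", function(x) standardGeneric("validFrames"))

#' @rdname EphysRecording-class
#' @export
setGeneric("voltageUV", function(x) standardGeneric("voltageUV"))

#' @rdname EphysRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EphysRecording-class
#' @export
setGeneric("tetrodeOf", function(x) standardGeneric("tetrodeOf"))

#' @rdname EphysRecording-class
#' @export
setGeneric("triggerChannel", function(x) standardGeneric("triggerChannel"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' @rdname BehaviorTrack-class
#' @export
setGeneric("trackXY", function(x) standardGeneric("trackXY"))

#' @rdname BehaviorTrack-class
#' @export
setGeneric("trackTimes", function(x, clock = c("video", "imaging"))
  standardGeneric("trackTimes"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("empiricalPValues", function(x) standardGeneric("empiricalPValues"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("significantFraction", function(x, shuffled = FALSE)
  standardGeneric("significantFraction"))
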