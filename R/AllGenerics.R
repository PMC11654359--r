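#' @import methods
NULL

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setGeneric("videoID", function(x) standardGeneric("videoID"))

#' @export
setGeneric("framesPerSecond", function(x) standardGeneric("framesPerSecond"))

#' @export
setGeneric("poseCoords", function(x) standardGeneric("poseCoords"))

#' @export
setGeneric("skeleton", function(x) standardGeneric("skeleton"))

#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @export
setGeneric("anchorHead", function(x) standardGeneric("anchorHead"))

#' @export
setGeneric("anchorBody", function(x) standardGeneric("anchorBody"))

#' @export
setGeneric("limbSides", function(x) standardGeneric("limbSides"))

#' @export
setGeneric("pixelsPerCm", function(x) standardGeneric("pixelsPerCm"))

#' @export
setGeneric("zoneBreaks", function(x) standardGeneric("zoneBreaks"))

#' @export
setGeneric("perSecond", function(x) standardGeneric("perSecond"))

#' @export
setGeneric("secondsPerZone", function(x) standardGeneric("secondsPerZone"))

#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @export
setGeneric("nodeSpeed", function(x) standardGeneric("nodeSpeed"))

#' @export
setGeneric("distancePerZone", function(x) standardGeneric("distancePerZone"))

#' @export
setGeneric("totalDistanceCm", function(x) standardGeneric("totalDistanceCm"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("retainedFrames", function(x) standardGeneric("retainedFrames"))

#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' @export
setGeneric("semanticMap", function(x) standardGeneric("semanticMap"))

#' @export
setGeneric("bouts", function(x) standardGeneric("bouts"))

#' @export
setGeneric("timePerBehavior", function(x) standardGeneric("timePerBehavior"))

#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @export
setGeneric("poseTrack", function(x) standardGeneric("poseTrack"))

#' @export
setGeneric("truthOccupancy", function(x) standardGeneric("truthOccupancy"))

#' @export
setGeneric("truthStates", function(x) standardGeneric("truthStates"))

#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
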