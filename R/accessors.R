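#' @describeIn PoseTrack-class number of frames
#' @param x object
#' @export
setMethod("nFrames", "PoseTrack", function(x) dim(x@coords)[1])

#' @describeIn PoseTrack-class number of nodes
#' @export
setMethod("nNodes", "PoseTrack", function(x) dim(x@coords)[2])

#' @describeIn PoseTrack-class session identifier
#' @export
setMethod("videoID", "PoseTrack", function(x) x@videoID)

#' @describeIn PoseTrack-class frames per second
#' @export
setMethod("framesPerSecond", "PoseTrack", function(x) x@fps)

#' @describeIn PoseTrack-class coordinate array (frames x nodes x 2)
#' @export
setMethod("poseCoords", "PoseTrack", function(x) x@coords)

#' @describeIn PoseTrack-class the skeleton definition
#' @export
setMethod("skeleton", "PoseTrack", function(x) x@skeleton)

#' @describeIn SkeletonDef-class ordered node names
#' @param x object
#' @export
setMethod("nodeNames", "SkeletonDef", function(x) x@nodeNames)

#' @describeIn PoseTrack-class node names of the skeleton
#' @export
setMethod("nodeNames", "PoseTrack", function(x) x@skeleton@nodeNames)

#' @describeIn SkeletonDef-class head anchor node
#' @export
setMethod("anchorHead", "SkeletonDef", function(x) x@anchorHead)

#' @describeIn SkeletonDef-class metathorax / body anchor node
#' @export
setMethod("anchorBody", "SkeletonDef", function(x) x@anchorBody)

#' @describeIn SkeletonDef-class left/right/midline map over nodes
#' @export
setMethod("limbSides", "SkeletonDef", function(x) x@limbSides)

#' @describeIn ArenaGeometry-class pixels per centimetre along the long axis
#' @param x object
#' @export
setMethod("pixelsPerCm", "ArenaGeometry",
  function(x) (x@xMaxPx - x@xMinPx) / x@lengthCm)

#' @describeIn ArenaGeometry-class zone boundary pixels (length nZones + 1)
#' @export
setMethod("zoneBreaks", "ArenaGeometry",
  function(x) seq(x@xMinPx, x@xMaxPx, length.out = x@nZones + 1L))

#' @describeIn ZoneOccupancySeries-class per-second zone labels
#' @param x object
#' @export
setMethod("perSecond", "ZoneOccupancySeries", function(x) x@perSecond)

#' @describeIn ZoneOccupancySeries-class seconds spent in each zone
#' @export
setMethod("secondsPerZone", "ZoneOccupancySeries", function(x) x@secondsPerZone)

#' @describeIn ZoneOccupancySeries-class session length in whole seconds
#' @export
setMethod("durationS", "ZoneOccupancySeries", function(x) x@durationS)

#' @describeIn KinematicsResult-class per-step node speeds (cm/s)
#' @param x object
#' @export
setMethod("nodeSpeed", "KinematicsResult", function(x) x@nodeSpeed)

#' @describeIn KinematicsResult-class cm travelled per zone
#' @export
setMethod("distancePerZone", "KinematicsResult", function(x) x@distancePerZone)

#' @describeIn KinematicsResult-class total path length (cm)
#' @export
setMethod("totalDistanceCm", "KinematicsResult", function(x) x@totalDistanceCm)

#' @describeIn FeatureMatrix-class the standardized matrix
#' @param x object
#' @export
setMethod("featureMatrix", "FeatureMatrix", function(x) x@mat)

#' @describeIn FeatureMatrix-class 0-based retained frame indices
#' @export
setMethod("retainedFrames", "FeatureMatrix", function(x) x@frames)

#' @describeIn EthogramResult-class per-frame cluster ids (0-based)
#' @param x object
#' @export
setMethod("frameLabels", "EthogramResult", function(x) x@labels)

#' @describeIn EthogramResult-class 0-based retained frame indices
#' @export
setMethod("retainedFrames", "EthogramResult", function(x) x@frames)

#' @describeIn EthogramResult-class cluster id to behavior name map
#' @export
setMethod("semanticMap", "EthogramResult", function(x) x@semanticMap)

#' @describeIn EthogramResult-class bout table (half-open frame runs)
#' @export
setMethod("bouts", "EthogramResult", function(x) x@bouts)

#' @describeIn EthogramResult-class seconds per behavior
#' @export
setMethod("timePerBehavior", "EthogramResult", function(x) x@timePerBehavior)

#' @describeIn EthogramResult-class per-frame 2-D embedding
#' @export
setMethod("embeddingCoords", "EthogramResult", function(x) x@embedding)

#' @describeIn SyntheticDataset-class the observed pose track
#' @param x object
#' @export
setMethod("poseTrack", "SyntheticDataset", function(x) x@track)

#' @describeIn SyntheticDataset-class ground-truth zone per second
#' @export
setMethod("truthOccupancy", "SyntheticDataset", function(x) x@truthOccupancy)

#' @describeIn SyntheticDataset-class ground-truth behavior per frame
#' @export
setMethod("truthStates", "SyntheticDataset", function(x) x@truthStates)

#' @describeIn SyntheticDataset-class exposure group label
#' @export
setMethod("groupLabel", "SyntheticDataset", function(x) x@group)
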