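#' Skeleton definition for a pose-tracked animal
#'
#' An ordered set of tracked anatomical landmarks ("nodes") together with
#' the two anchor nodes the pipeline relies on: the head (used for zone
#' occupancy scoring) and the metathorax (the central body anchor used for
#' distance and velocity), plus a left/right/midline assignment for every
#' node so that lateralized limb movement can be told apart.
#'
#' @slot nodeNames character vector of unique, non-empty node names; the
#'   order defines the column order of every coordinate array.
#' @slot anchorHead name of the head node (must be in \code{nodeNames}).
#' @slot anchorBody name of the metathorax / body-centroid node.
#' @slot limbSides named character vector mapping every node to
#'   \code{"left"}, \code{"right"} or \code{"midline"}.
#'
#' @seealso [cockroachSkeleton()] for the default 27-node skeleton.
#' @export
setClass("SkeletonDef",
  representation(
    nodeNames = "character",
    anchorHead = "character",
    anchorBody = "character",
    limbSides = "character"
  )
)

setValidity("SkeletonDef", function(object) {
  nn <- object@nodeNames
  msg <- character()
  if (length(nn) == 0L || anyNA(nn) || any(!nzchar(nn))) {
    msg <- c(msg, "node names must be non-empty strings")
  }
  if (anyDuplicated(nn)) msg <- c(msg, "node names must be unique")
  if (length(object@anchorHead) != 1L || !(object@anchorHead %in% nn)) {
    msg <- c(msg, "anchorHead must be a single member of nodeNames")
  }
  if (length(object@anchorBody) != 1L || !(object@anchorBody %in% nn)) {
    msg <- c(msg, "anchorBody must be a single member of nodeNames")
  }
  ls <- object@limbSides
  if (!setequal(names(ls), nn)) {
    msg <- c(msg, "limbSides must be named by exactly the node names")
  }
  if (!all(ls %in% c("left", "right", "midline"))) {
    msg <- c(msg, "limbSides values must be 'left', 'right' or 'midline'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SkeletonDef
#'
#' @param nodeNames ordered character vector of node names.
#' @param anchorHead head node name.
#' @param anchorBody metathorax (body-centroid) node name.
#' @param limbSides named character vector over all nodes with values
#'   \code{"left"}, \code{"right"} or \code{"midline"}. If omitted, sides
#'   are guessed from a leading \code{"l_"}/\code{"r_"} prefix, anything
#'   else being midline.
#' @return a validated [SkeletonDef-class] object.
#' @export
SkeletonDef <- function(nodeNames, anchorHead, anchorBody, limbSides = NULL) {
  if (is.null(limbSides)) {
    limbSides <- ifelse(startsWith(nodeNames, "l_"), "left",
      ifelse(startsWith(nodeNames, "r_"), "right", "midline"))
    names(limbSides) <- nodeNames
  }
  new("SkeletonDef",
    nodeNames = as.character(nodeNames),
    anchorHead = anchorHead, anchorBody = anchorBody,
    limbSides = limbSides[nodeNames])
}

#' Pose track: per-frame x/y pixel coordinates for every node
#'
#' The pipeline's universal input. Coordinates are image pixels with the
#' origin at the top-left corner, x increasing rightward along the runway's
#' long axis and y increasing downward; frames are 0-based in all reported
#' frame indices. A missing detection is an \code{NA} pair (x and y are
#' always missing together).
#'
#' @slot videoID identifier of the source video / session.
#' @slot fps frames per second (> 0).
#' @slot coords numeric array \code{n_frames x n_nodes x 2}; third dimension
#'   is \code{c("x", "y")}.
#' @slot skeleton the [SkeletonDef-class] the columns follow.
#' @export
setClass("PoseTrack",
  representation(
    videoID = "character",
    fps = "numeric",
    coords = "array",
    skeleton = "SkeletonDef"
  )
)

setValidity("PoseTrack", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 2L) {
    return("coords must be an n_frames x n_nodes x 2 array")
  }
  if (d[2] != length(object@skeleton@nodeNames)) {
    msg <- c(msg, sprintf(
      "coords has %d node columns but the skeleton defines %d nodes",
      d[2], length(object@skeleton@nodeNames)))
  }
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0) {
    msg <- c(msg, "fps must be a single positive finite number")
  }
  cx <- object@coords[, , 1, drop = FALSE]
  cy <- object@coords[, , 2, drop = FALSE]
  if (any(is.nan(cx) & !is.na(cx)) ||
      any(!is.na(cx) & !is.finite(cx)) || any(!is.na(cy) & !is.finite(cy))) {
    msg <- c(msg, "non-missing coordinates must be finite")
  }
  if (any(is.na(cx) != is.na(cy))) {
    msg <- c(msg, "x and y of a node must be missing together")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoseTrack
#'
#' @param coords numeric array \code{n_frames x n_nodes x 2} of pixel
#'   coordinates; \code{NA} marks a missing detection (x and y together).
#' @param skeleton a [SkeletonDef-class]; defaults to
#'   [cockroachSkeleton()] when the array has 27 node columns.
#' @param fps frames per second; default 60.
#' @param videoID session identifier.
#' @return a validated [PoseTrack-class].
#' @export
PoseTrack <- function(coords, skeleton = NULL, fps = 60, videoID = "session") {
  if (is.null(skeleton)) skeleton <- cockroachSkeleton()
  dimnames(coords) <- list(NULL, skeleton@nodeNames, c("x", "y"))
  new("PoseTrack", videoID = videoID, fps = as.numeric(fps),
    coords = coords, skeleton = skeleton)
}

#' Arena geometry of the linear track
#'
#' Describes the runway rectangle in image pixels, its physical size, and
#' its partition into equal zones (quadrants) along the long axis. The
#' pixel-to-centimetre calibration is derived from the long axis only:
#' \code{pixelsPerCm = (xMaxPx - xMinPx) / lengthCm}.
#'
#' @slot xMinPx,xMaxPx runway extent along the long (x) axis, pixels.
#' @slot yMinPx,yMaxPx runway extent across the short (y) axis, pixels.
#' @slot lengthCm physical long-axis length in cm (default 60.96 = 24 in).
#' @slot widthCm physical short-axis width in cm (default 10.16 = 4 in).
#' @slot nZones number of equal zones along x (default 4).
#' @slot portZone index of the zone holding the exposure port (default 4).
#' @export
setClass("ArenaGeometry",
  representation(
    xMinPx = "numeric", xMaxPx = "numeric",
    yMinPx = "numeric", yMaxPx = "numeric",
    lengthCm = "numeric", widthCm = "numeric",
    nZones = "integer", portZone = "integer"
  )
)

setValidity("ArenaGeometry", function(object) {
  msg <- character()
  if (!(object@xMaxPx > object@xMinPx)) msg <- c(msg, "xMaxPx must exceed xMinPx")
  if (!(object@yMaxPx > object@yMinPx)) msg <- c(msg, "yMaxPx must exceed yMinPx")
  if (object@nZones < 2L) msg <- c(msg, "nZones must be at least 2")
  if (object@lengthCm <= 0 || object@widthCm <= 0) {
    msg <- c(msg, "physical dimensions must be positive")
  }
  if (object@portZone < 1L || object@portZone > object@nZones) {
    msg <- c(msg, "portZone must be one of the zones")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ArenaGeometry
#'
#' Defaults describe the 24 x 4 inch runway divided into four quadrants
#' with the exposure port in quadrant 4, imaged at 20 px/cm.
#'
#' @param xMinPx,xMaxPx,yMinPx,yMaxPx runway rectangle in pixels.
#' @param lengthCm,widthCm physical size in cm.
#' @param nZones number of equal zones along the long axis.
#' @param portZone zone containing the exposure port.
#' @return a validated [ArenaGeometry-class].
#' @export
ArenaGeometry <- function(xMinPx = 0, xMaxPx = 1219.2,
                          yMinPx = 0, yMaxPx = 203.2,
                          lengthCm = 60.96, widthCm = 10.16,
                          nZones = 4L, portZone = 4L) {
  new("ArenaGeometry",
    xMinPx = as.numeric(xMinPx), xMaxPx = as.numeric(xMaxPx),
    yMinPx = as.numeric(yMinPx), yMaxPx = as.numeric(yMaxPx),
    lengthCm = as.numeric(lengthCm), widthCm = as.numeric(widthCm),
    nZones = as.integer(nZones), portZone = as.integer(portZone))
}

#' Per-second zone occupancy of a session
#'
#' One zone label per whole second of the session (the hand-scoring
#' convention: each second scored 1..nZones by the position of the head),
#' \code{NA} where the anchor was never detected during that second.
#'
#' @slot perSecond integer vector of zone labels, \code{NA} = unscorable.
#' @slot secondsPerZone named numeric, seconds spent per zone.
#' @slot durationS session length in whole seconds.
#' @slot nZones number of zones.
#' @export
setClass("ZoneOccupancySeries",
  representation(
    perSecond = "integer",
    secondsPerZone = "numeric",
    durationS = "numeric",
    nZones = "integer"
  )
)

setValidity("ZoneOccupancySeries", function(object) {
  msg <- character()
  ps <- object@perSecond
  if (length(ps) != object@durationS) {
    msg <- c(msg, "perSecond length must equal durationS")
  }
  ok <- ps[!is.na(ps)]
  if (length(ok) && (any(ok < 1L) || any(ok > object@nZones))) {
    msg <- c(msg, "zone labels must lie in 1..nZones")
  }
  if (length(object@secondsPerZone) != object@nZones) {
    msg <- c(msg, "secondsPerZone must have one entry per zone")
  }
  tot <- sum(object@secondsPerZone) + sum(is.na(ps))
  if (abs(tot - object@durationS) > 1e-9) {
    msg <- c(msg, "seconds per zone plus missing seconds must equal duration")
  }
  if (length(msg)) msg else TRUE
})

#' Kinematics of a pose track in physical units
#'
#' @slot nodeSpeed numeric matrix \code{(n_frames - 1) x n_nodes} of speeds
#'   in cm/s; row i is the speed over the step from frame i-1 to frame i
#'   (0-based), \code{NA} where either endpoint is missing.
#' @slot distancePerZone named numeric, cm travelled by the distance node
#'   attributed to the zone of each step's starting frame.
#' @slot totalDistanceCm total path length of the distance node, cm.
#' @slot meanSpeedPerNode named numeric, cm/s.
#' @slot meanSpeedOverall single numeric, cm/s.
#' @slot distanceNode node used for distance accumulation.
#' @export
setClass("KinematicsResult",
  representation(
    nodeSpeed = "matrix",
    distancePerZone = "numeric",
    totalDistanceCm = "numeric",
    meanSpeedPerNode = "numeric",
    meanSpeedOverall = "numeric",
    distanceNode = "character"
  )
)

#' Standardized per-frame feature matrix for behavior clustering
#'
#' Rows are retained frames (frames where every feature is observed after
#' any gap-filling); columns are per-node speed (cm/s) followed by per-node
#' x and y position (cm), each column z-scored. The transform is recorded
#' so features can be mapped back to physical units.
#'
#' @slot mat numeric matrix, no missing entries, \code{3 * n_nodes} columns.
#' @slot frames 0-based indices of the retained frames.
#' @slot center,scale per-column standardization record (scale 0 marks a
#'   constant column whose standardized values are 0).
#' @slot fps frames per second of the source track.
#' @slot nodeNames node names of the source skeleton.
#' @export
setClass("FeatureMatrix",
  representation(
    mat = "matrix",
    frames = "integer",
    center = "numeric",
    scale = "numeric",
    fps = "numeric",
    nodeNames = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (anyNA(object@mat)) msg <- c(msg, "feature matrix must have no missing entries")
  if (ncol(object@mat) != 3L * length(object@nodeNames)) {
    msg <- c(msg, "feature matrix must have 3 columns per node")
  }
  if (nrow(object@mat) != length(object@frames)) {
    msg <- c(msg, "one retained frame index per row required")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters for 2-D embedding of behavior features
#'
#' Defaults follow the hyperparameters used for the study-style UMAP
#' visualization: 2 components, 15 neighbors, Euclidean distance, minimum
#' distance 0.1, spread 1.0, random state 42.
#'
#' @slot method \code{"pca"} or \code{"umap"}.
#' @slot nComponents number of output dimensions.
#' @slot nNeighbors UMAP neighborhood size.
#' @slot minDist UMAP minimum distance (in \code{[0, spread]}).
#' @slot spread UMAP spread.
#' @slot seed random seed.
#' @export
setClass("EmbeddingParams",
  representation(
    method = "character",
    nComponents = "integer",
    nNeighbors = "integer",
    minDist = "numeric",
    spread = "numeric",
    seed = "integer"
  )
)

setValidity("EmbeddingParams", function(object) {
  msg <- character()
  if (!object@method %in% c("pca", "umap")) {
    msg <- c(msg, "method must be 'pca' or 'umap'")
  }
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (object@nNeighbors < 2L) msg <- c(msg, "nNeighbors must be >= 2")
  if (object@minDist < 0 || object@minDist > object@spread) {
    msg <- c(msg, "minDist must lie in [0, spread]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct EmbeddingParams
#' @param method \code{"pca"} (default) or \code{"umap"}.
#' @param nComponents,nNeighbors,minDist,spread,seed see
#'   [EmbeddingParams-class].
#' @return validated [EmbeddingParams-class].
#' @export
EmbeddingParams <- function(method = c("pca", "umap"), nComponents = 2,
                            nNeighbors = 15, minDist = 0.1, spread = 1.0,
                            seed = 42) {
  method <- match.arg(method)
  new("EmbeddingParams", method = method,
    nComponents = as.integer(nComponents), nNeighbors = as.integer(nNeighbors),
    minDist = as.numeric(minDist), spread = as.numeric(spread),
    seed = as.integer(seed))
}

#' Ethogram of a session
#'
#' Per-frame behavior cluster labels with a semantic interpretation,
#' bout segmentation, time per behavior and a 2-D embedding.
#'
#' @slot labels integer cluster ids in \code{0..k-1}, one per retained frame.
#' @slot k number of clusters.
#' @slot semanticMap named character mapping cluster id (as character) to
#'   a behavior name; empty when no semantic labeling was requested.
#' @slot bouts data.frame with 0-based half-open \code{start}, \code{end}
#'   frame-row indices and \code{label} (plus \code{behavior} when mapped).
#' @slot timePerBehavior named numeric, seconds per behavior (or per raw
#'   cluster when unmapped).
#' @slot embedding numeric matrix of per-frame 2-D coordinates (0 rows when
#'   not computed).
#' @slot frames 0-based retained frame indices (parallel to labels).
#' @slot seed seed used for clustering/embedding.
#' @slot tie logical; TRUE when semantic labeling hit a tie broken by
#'   cluster id.
#' @export
setClass("EthogramResult",
  representation(
    labels = "integer",
    k = "integer",
    semanticMap = "character",
    bouts = "data.frame",
    timePerBehavior = "numeric",
    embedding = "matrix",
    frames = "integer",
    seed = "integer",
    tie = "logical"
  )
)

setValidity("EthogramResult", function(object) {
  msg <- character()
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) >= object@k)) {
    msg <- c(msg, "labels must lie in 0..k-1")
  }
  b <- object@bouts
  if (nrow(b)) {
    if (b$start[1] != 0L || b$end[nrow(b)] != length(object@labels) ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))) {
      msg <- c(msg, "bouts must tile the retained frames")
    }
    if (nrow(b) > 1 && any(b$label[-1] == b$label[-nrow(b)])) {
      msg <- c(msg, "consecutive bouts must differ in label")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Regime (behavior state) parameters for the locomotion simulator
#'
#' One row per behavior state giving the state-conditioned kinematics of
#' the Markov-chain generator.
#'
#' @param state character: resting, scurrying, left_leg, right_leg.
#' @param bodyMean,bodySd body (centroid) speed mean and sd, cm/s.
#' @param limbAmp limb oscillation amplitude, cm.
#' @param limbSide which side's legs oscillate: left, right, both, none.
#' @param dwell per-frame self-transition probability in (0, 1).
#' @return data.frame of class use by [SessionConfig()].
#' @export
RegimeParams <- function(state = c("resting", "scurrying", "left_leg", "right_leg"),
                         bodyMean = c(0.05, 6.0, 0.10, 0.10),
                         bodySd = c(0.02, 0.8, 0.05, 0.05),
                         limbAmp = c(0, 0, 0.3, 0.3),
                         limbSide = c("none", "both", "left", "right"),
                         dwell = c(0.995, 0.995, 0.99, 0.99)) {
  stopifnot(all(bodyMean >= 0), all(bodySd >= 0),
    all(dwell > 0 & dwell < 1),
    bodyMean[state == "scurrying"] > bodyMean[state == "resting"])
  data.frame(state = state, bodyMean = bodyMean, bodySd = bodySd,
    limbAmp = limbAmp, limbSide = limbSide, dwell = dwell,
    stringsAsFactors = FALSE)
}

#' Configuration of one simulated session
#'
#' @slot durationS session length in seconds (default 120, the 2-minute
#'   trial length).
#' @slot fps frames per second (default 60, the stated recording rate).
#' @slot arena [ArenaGeometry-class].
#' @slot skeleton [SkeletonDef-class] (default: 27-node cockroach).
#' @slot regimes regime parameter table from [RegimeParams()].
#' @slot portBias real in \code{[-1, 1]}: attraction (+) or aversion (-)
#'   toward the port zone, applied as a bias on heading choice while moving.
#' @slot noiseSdPx Gaussian detection noise sd in pixels (default 0; the
#'   generator's core product is ground truth, corruption is opt-in).
#' @slot missingRate independent per-node-frame dropout probability.
#' @slot seed integer seed driving all randomness.
#' @export
setClass("SessionConfig",
  representation(
    durationS = "numeric",
    fps = "numeric",
    arena = "ArenaGeometry",
    skeleton = "SkeletonDef",
    regimes = "data.frame",
    portBias = "numeric",
    noiseSdPx = "numeric",
    missingRate = "numeric",
    seed = "integer"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (abs(object@portBias) > 1) msg <- c(msg, "portBias must lie in [-1, 1]")
  if (object@noiseSdPx < 0) msg <- c(msg, "noiseSdPx must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msg <- c(msg, "missingRate must lie in [0, 1)")
  }
  req <- c("state", "bodyMean", "bodySd", "limbAmp", "limbSide", "dwell")
  if (!all(req %in% names(object@regimes)) || nrow(object@regimes) != 4L) {
    msg <- c(msg, "regimes must be a 4-state RegimeParams table")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SessionConfig
#'
#' @param durationS,fps,arena,skeleton,regimes,portBias,noiseSdPx,missingRate,seed
#'   see [SessionConfig-class].
#' @return validated [SessionConfig-class].
#' @export
SessionConfig <- function(durationS = 120, fps = 60, arena = ArenaGeometry(),
                          skeleton = cockroachSkeleton(),
                          regimes = RegimeParams(), portBias = 0,
                          noiseSdPx = 0, missingRate = 0, seed = 1L) {
  new("SessionConfig", durationS = as.numeric(durationS), fps = as.numeric(fps),
    arena = arena, skeleton = skeleton, regimes = regimes,
    portBias = as.numeric(portBias), noiseSdPx = as.numeric(noiseSdPx),
    missingRate = as.numeric(missingRate), seed = as.integer(seed))
}

#' Simulated session with ground truth
#'
#' @slot track observed [PoseTrack-class] (noise/dropout applied).
#' @slot truthOccupancy integer zone label per whole second, from the
#'   noiseless head trajectory.
#' @slot truthStates character behavior state per frame.
#' @slot group exposure group label.
#' @slot config the [SessionConfig-class] that produced it.
#' @export
setClass("SyntheticDataset",
  representation(
    track = "PoseTrack",
    truthOccupancy = "integer",
    truthStates = "character",
    group = "character",
    config = "SessionConfig"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  nf <- dim(object@track@coords)[1]
  if (length(object@truthStates) != nf) {
    msg <- c(msg, "one truth state per frame required")
  }
  if (length(object@truthOccupancy) != floor(nf / object@track@fps)) {
    msg <- c(msg, "one truth occupancy label per whole second required")
  }
  if (length(msg)) msg else TRUE
})

#' Report of an assumption-gated group comparison
#'
#' @slot branch \code{"parametric"} or \code{"nonparametric"}.
#' @slot gateShapiro named numeric, Shapiro-Wilk p per group.
#' @slot gateLevene Levene (median-centred) p.
#' @slot omnibus list with \code{method}, \code{statistic}, \code{p.value}.
#' @slot pairwise data.frame: \code{group1}, \code{group2},
#'   \code{statistic}, \code{p}, \code{p.adj}, \code{method}.
#' @slot alpha gate significance level.
#' @export
setClass("ComparisonReport",
  representation(
    branch = "character",
    gateShapiro = "numeric",
    gateLevene = "numeric",
    omnibus = "list",
    pairwise = "data.frame",
    alpha = "numeric"
  )
)

#' Hand-vs-machine scoring agreement report
#'
#' @slot cells data.frame with one row per (session x zone) cell:
#'   \code{session}, \code{zone}, \code{hand}, \code{machine},
#'   \code{diffPct} (normalized absolute difference as percent of session
#'   length).
#' @slot meanAbsErrorPct mean of \code{diffPct}.
#' @slot pairedT list with \code{statistic} and \code{p.value} of the
#'   paired t test across cells (p = 1, statistic NA for identical tables).
#' @slot durationS normalizing session length, seconds.
#' @export
setClass("AgreementReport",
  representation(
    cells = "data.frame",
    meanAbsErrorPct = "numeric",
    pairedT = "list",
    durationS = "numeric"
  )
)
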