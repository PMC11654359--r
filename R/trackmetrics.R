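#' Assign x pixel coordinates to track zones
#'
#' The runway's long axis is partitioned into \code{nZones} equal
#' half-open intervals \code{[b_k, b_{k+1})}. Coordinates left of the
#' runway clamp to zone 1 and coordinates at or beyond the far edge clamp
#' to the last zone, so the function is total on finite inputs.
#'
#' @param xPx numeric vector of x pixel coordinates (finite; \code{NA}
#'   passes through as \code{NA}).
#' @param geometry an [ArenaGeometry-class].
#' @return integer vector of zone labels in \code{1..nZones}.
#' @examples
#' g <- ArenaGeometry(xMinPx = 0, xMaxPx = 400)
#' assignZone(c(50, 100, 399.9, 405, -3), g)  # 1 2 4 4 1
#' @export
assignZone <- function(xPx, geometry) {
  if (any(is.nan(xPx)) || any(is.infinite(xPx))) {
    stop("x coordinates must be finite")
  }
  br <- zoneBreaks(geometry)
  z <- findInterval(xPx, br, rightmost.closed = FALSE, left.open = FALSE)
  z <- pmin(pmax(z, 1L), geometry@nZones)
  z[is.na(xPx)] <- NA_integer_
  as.integer(z)
}

#' Score per-second zone occupancy from an anchor node
#'
#' Replicates the hand-scoring protocol: the session is split into whole
#' seconds (second s covers frames \code{floor(s * fps)} to
#' \code{floor((s + 1) * fps) - 1}, 0-based) and each second is labeled with
#' the zone holding the anchor node — by majority vote over the frames in
#' which the anchor was detected. Ties go to the previous second's zone
#' when it is among the tied zones, otherwise to the lowest zone index. A
#' second with no detected anchor frame is \code{NA}. A trailing partial
#' second is not scored.
#'
#' @param track a [PoseTrack-class].
#' @param geometry an [ArenaGeometry-class].
#' @param anchor anchor node name; default the skeleton's head.
#' @return a [ZoneOccupancySeries-class].
#' @export
scoreOccupancy <- function(track, geometry, anchor = anchorHead(skeleton(track))) {
  nn <- nodeNames(track)
  if (!anchor %in% nn) stop("unknown anchor node: ", anchor)
  fps <- track@fps
  nSec <- floor(nFrames(track) / fps)
  x <- track@coords[, match(anchor, nn), 1]
  zones <- assignZone(x, geometry)
  per <- rep(NA_integer_, nSec)
  prev <- NA_integer_
  for (s in seq_len(nSec)) {
    idx <- (floor((s - 1) * fps) + 1L):floor(s * fps)
    zs <- zones[idx]
    zs <- zs[!is.na(zs)]
    if (!length(zs)) { prev <- NA_integer_; next }
    counts <- tabulate(zs, nbins = geometry@nZones)
    cand <- which(counts == max(counts))
    per[s] <- if (!is.na(prev) && prev %in% cand) prev else min(cand)
    prev <- per[s]
  }
  spz <- as.numeric(tabulate(per[!is.na(per)], nbins = geometry@nZones))
  names(spz) <- paste0("Q", seq_len(geometry@nZones))
  new("ZoneOccupancySeries", perSecond = per, secondsPerZone = spz,
    durationS = as.numeric(nSec), nZones = geometry@nZones)
}

#' Compute speeds and distance travelled in physical units
#'
#' Per-node speed over the step from frame i to i+1 is the Euclidean pixel
#' displacement divided by \code{pixelsPerCm(geometry)} and multiplied by
#' fps (cm/s); it is \code{NA} when either endpoint is missing. The
#' distance node's per-step displacements are accumulated into the zone of
#' the step's starting frame; steps with a missing endpoint contribute
#' nothing.
#'
#' @param track a [PoseTrack-class] with at least 2 frames.
#' @param geometry an [ArenaGeometry-class].
#' @param distanceNode node used for distance; default the metathorax
#'   (body anchor).
#' @return a [KinematicsResult-class].
#' @export
computeKinematics <- function(track, geometry,
                              distanceNode = anchorBody(skeleton(track))) {
  nn <- nodeNames(track)
  if (!distanceNode %in% nn) stop("unknown distance node: ", distanceNode)
  ppc <- pixelsPerCm(geometry)
  xy <- track@coords
  nf <- dim(xy)[1]
  if (nf < 2L) stop("kinematics require at least 2 frames")
  dx <- xy[-1L, , 1, drop = FALSE] - xy[-nf, , 1, drop = FALSE]
  dy <- xy[-1L, , 2, drop = FALSE] - xy[-nf, , 2, drop = FALSE]
  dispCm <- sqrt(dx^2 + dy^2)[, , 1] / ppc
  dispCm <- matrix(dispCm, nf - 1L, length(nn), dimnames = list(NULL, nn))
  speed <- dispCm * track@fps
  j <- match(distanceNode, nn)
  stepCm <- dispCm[, j]
  startZone <- assignZone(xy[-nf, j, 1], geometry)
  keep <- !is.na(stepCm) & !is.na(startZone)
  dpz <- vapply(seq_len(geometry@nZones), function(z) {
    sum(stepCm[keep & startZone == z])
  }, numeric(1))
  names(dpz) <- paste0("Q", seq_len(geometry@nZones))
  meanPerNode <- colMeans(speed, na.rm = TRUE)
  meanPerNode[is.nan(meanPerNode)] <- NA_real_
  allSpeed <- speed[!is.na(speed)]
  new("KinematicsResult", nodeSpeed = speed, distancePerZone = dpz,
    totalDistanceCm = sum(dpz), meanSpeedPerNode = meanPerNode,
    meanSpeedOverall = if (length(allSpeed)) mean(allSpeed) else NA_real_,
    distanceNode = distanceNode)
}

#' Occupancy heat map of a node over the arena
#'
#' A 2-D histogram of frame counts over the runway rectangle. Positions
#' outside the rectangle are clamped into the edge bins, so the grid total
#' equals the number of frames in which the node was detected.
#'
#' @param track a [PoseTrack-class].
#' @param geometry an [ArenaGeometry-class].
#' @param node node to bin; default the metathorax.
#' @param binsX,binsY grid size (>= 1); defaults 48 x 8.
#' @return integer matrix \code{binsY x binsX} (rows = y bins, top first).
#' @export
occupancyHeatmap <- function(track, geometry,
                             node = anchorBody(skeleton(track)),
                             binsX = 48L, binsY = 8L) {
  stopifnot(binsX >= 1L, binsY >= 1L)
  nn <- nodeNames(track)
  if (!node %in% nn) stop("unknown node: ", node)
  j <- match(node, nn)
  x <- track@coords[, j, 1]
  y <- track@coords[, j, 2]
  ok <- !is.na(x)
  bx <- seq(geometry@xMinPx, geometry@xMaxPx, length.out = binsX + 1L)
  by <- seq(geometry@yMinPx, geometry@yMaxPx, length.out = binsY + 1L)
  ix <- pmin(pmax(findInterval(x[ok], bx, rightmost.closed = TRUE), 1L), binsX)
  iy <- pmin(pmax(findInterval(y[ok], by, rightmost.closed = TRUE), 1L), binsY)
  grid <- matrix(0L, binsY, binsX)
  for (i in seq_along(ix)) grid[iy[i], ix[i]] <- grid[iy[i], ix[i]] + 1L
  grid
}
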