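#' Read a pose track from a SLEAP-style analysis HDF5 file
#'
#' Expects the analysis export layout: a \code{tracks} dataset of per-frame
#' x/y coordinates for every node (single animal) and a \code{node_names}
#' dataset giving the node order. Missing detections (NaN in the file) are
#' mapped to the package's \code{NA} missing marker, with x and y of a node
#' always missing together. The frame rate is taken from a \code{video_fps}
#' (or \code{fps}) dataset when present, otherwise \code{defaultFps}.
#'
#' @param path HDF5 file path.
#' @param skeletonOverride optional [SkeletonDef-class]; must match the
#'   file's node count. When absent, a skeleton is built from the file's
#'   node names (the default cockroach anchors when they exist, else the
#'   first and middle nodes).
#' @param defaultFps frame rate used when the file carries none; default 60.
#' @return a validated [PoseTrack-class].
#' @examples
#' f <- tempfile(fileext = ".h5")
#' tr <- PoseTrack(array(1, c(3, 27, 2)), fps = 60)
#' writePoseH5(tr, f)
#' tr2 <- readPoseH5(f)
#' @export
readPoseH5 <- function(path, skeletonOverride = NULL, defaultFps = 60) {
  if (!file.exists(path)) stop("file not found: ", path)
  contents <- rhdf5::h5ls(path)
  have <- contents$name[contents$group == "/"]
  for (req in c("tracks", "node_names")) {
    if (!req %in% have) {
      stop("not a pose analysis file: missing dataset '", req, "' in ", path)
    }
  }
  on.exit(rhdf5::H5close(), add = TRUE)
  nodeNamesRaw <- as.character(rhdf5::h5read(path, "node_names"))
  arr <- rhdf5::h5read(path, "tracks")
  arr <- asFrameNodeXY(arr, length(nodeNamesRaw))
  fps <- defaultFps
  if ("video_fps" %in% have) fps <- as.numeric(rhdf5::h5read(path, "video_fps"))
  else if ("fps" %in% have) fps <- as.numeric(rhdf5::h5read(path, "fps"))
  vid <- if ("video_path" %in% have) {
    as.character(rhdf5::h5read(path, "video_path"))[1]
  } else basename(path)
  skel <- skeletonOverride
  if (is.null(skel)) {
    skel <- skeletonFromNames(nodeNamesRaw)
  } else if (length(skel@nodeNames) != length(nodeNamesRaw)) {
    stop("skeleton override has ", length(skel@nodeNames),
      " nodes but file has ", length(nodeNamesRaw))
  }
  arr[is.nan(arr)] <- NA_real_
  # enforce pairwise missingness
  bad <- is.na(arr[, , 1, drop = FALSE]) | is.na(arr[, , 2, drop = FALSE])
  arr[, , 1][bad[, , 1]] <- NA_real_
  arr[, , 2][bad[, , 1]] <- NA_real_
  PoseTrack(arr, skeleton = skel, fps = fps, videoID = vid)
}

# Coerce a read tracks dataset to n_frames x n_nodes x 2. The SLEAP
# analysis layout is (tracks, 2, nodes, frames) in C order, which rhdf5
# reads as (frames, nodes, 2, tracks); a singleton track axis is dropped.
asFrameNodeXY <- function(arr, nNodes) {
  d <- dim(arr)
  if (length(d) == 4L) {
    if (d[4] != 1L) stop("multi-animal track files are not supported")
    arr <- array(arr, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("tracks dataset must have 3 or 4 dimensions")
  if (d[2] == nNodes && d[3] == 2L) return(arr)
  if (d[1] == 2L && d[2] == nNodes) return(aperm(arr, c(3, 2, 1)))
  stop("tracks dataset dimensions ", paste(d, collapse = "x"),
    " do not match ", nNodes, " nodes")
}

skeletonFromNames <- function(nn) {
  head <- if ("head" %in% nn) "head" else nn[1]
  body <- if ("metathorax" %in% nn) "metathorax" else nn[max(1L, length(nn) %/% 2L)]
  SkeletonDef(nn, anchorHead = head, anchorBody = body)
}

#' Write a pose track as a SLEAP-style analysis HDF5 file
#'
#' Produces a file readable by [readPoseH5()] with bit-equal coordinates:
#' datasets \code{tracks} (single animal, NaN for missing), \code{node_names},
#' \code{video_fps} and \code{video_path}.
#'
#' @param track a [PoseTrack-class].
#' @param path output file path (overwritten if present).
#' @return \code{path}, invisibly.
#' @export
writePoseH5 <- function(track, path) {
  validObject(track)
  if (file.exists(path)) unlink(path)
  ok <- try(rhdf5::h5createFile(path), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path)) {
    stop("cannot write pose file: ", path)
  }
  on.exit(rhdf5::H5close(), add = TRUE)
  arr <- track@coords
  dimnames(arr) <- NULL
  arr[is.na(arr)] <- NaN
  d <- dim(arr)
  # R dims (frames, nodes, 2, 1) -> C-order shape (1, 2, nodes, frames)
  rhdf5::h5createDataset(path, "tracks", dims = c(d, 1L),
    storage.mode = "double")
  if (d[1] > 0L) rhdf5::h5write(array(arr, c(d, 1L)), path, "tracks")
  rhdf5::h5write(track@skeleton@nodeNames, path, "node_names")
  rhdf5::h5write(track@fps, path, "video_fps")
  rhdf5::h5write(track@videoID, path, "video_path")
  invisible(path)
}

#' Export a pose track as a flat CSV datasheet
#'
#' One row per frame with columns \code{video_id}, \code{frame} (0-based),
#' \code{time_s} (= frame / fps), then \code{<node>_x}, \code{<node>_y} for
#' every node. Missing detections become empty cells.
#'
#' @param track a [PoseTrack-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportDatasheet <- function(track, path) {
  validObject(track)
  nf <- nFrames(track)
  nn <- nodeNames(track)
  xy <- track@coords
  wide <- matrix(NA_real_, nf, 2L * length(nn))
  wide[, seq(1L, by = 2L, length.out = length(nn))] <- xy[, , 1]
  wide[, seq(2L, by = 2L, length.out = length(nn))] <- xy[, , 2]
  colnames(wide) <- as.vector(rbind(paste0(nn, "_x"), paste0(nn, "_y")))
  frame <- seq_len(nf) - 1L
  df <- data.frame(video_id = rep(track@videoID, nf), frame = frame,
    time_s = frame / track@fps, check.names = FALSE)
  df <- cbind(df, as.data.frame(wide, check.names = FALSE))
  ok <- try(utils::write.csv(df, path, row.names = FALSE, na = ""),
    silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write datasheet: ", path)
  invisible(path)
}

#' Re-import a datasheet written by exportDatasheet
#'
#' @param path CSV path.
#' @param skeleton optional [SkeletonDef-class]; by default rebuilt from
#'   the column names.
#' @param fps frame rate; by default recovered from the \code{time_s}
#'   column (60 when the sheet has fewer than two frames).
#' @return a [PoseTrack-class].
#' @export
readDatasheet <- function(path, skeleton = NULL, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- colnames(df)
  xcols <- grep("_x$", cn, value = TRUE)
  nn <- sub("_x$", "", xcols)
  nf <- nrow(df)
  if (is.null(fps)) {
    fps <- if (nf >= 2L) 1 / (df$time_s[2] - df$time_s[1]) else 60
  }
  arr <- array(NA_real_, c(nf, length(nn), 2))
  arr[, , 1] <- as.matrix(df[, paste0(nn, "_x"), drop = FALSE])
  arr[, , 2] <- as.matrix(df[, paste0(nn, "_y"), drop = FALSE])
  bad <- is.na(arr[, , 1]) | is.na(arr[, , 2])
  arr[, , 1][bad] <- NA_real_
  arr[, , 2][bad] <- NA_real_
  if (is.null(skeleton)) skeleton <- skeletonFromNames(nn)
  PoseTrack(arr, skeleton = skeleton, fps = fps,
    videoID = if (nf > 0) as.character(df$video_id[1]) else basename(path))
}

#' Interpolate short detection gaps
#'
#' Per node, interior runs of missing frames no longer than
#' \code{maxGapFrames} are filled by linear interpolation between the
#' flanking present coordinates; longer runs and leading/trailing runs are
#' left missing, and present values are never altered. Typical use is
#' repairing single-frame dropouts where a joint was briefly obscured.
#'
#' @param track a [PoseTrack-class].
#' @param maxGapFrames maximum gap length to fill (>= 0); 0 is a no-op.
#' @return a repaired [PoseTrack-class].
#' @export
fillMissing <- function(track, maxGapFrames) {
  stopifnot(maxGapFrames >= 0)
  if (maxGapFrames == 0 || nFrames(track) == 0) return(track)
  arr <- track@coords
  nf <- dim(arr)[1]
  for (j in seq_len(dim(arr)[2])) {
    miss <- is.na(arr[, j, 1])
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      s <- starts[i]; e <- ends[i]
      if (s == 1L || e == nf) next            # leading/trailing gap
      if (r$lengths[i] > maxGapFrames) next
      w <- (seq(s, e) - (s - 1L)) / (e + 1L - (s - 1L))
      for (k in 1:2) {
        arr[s:e, j, k] <- arr[s - 1L, j, k] * (1 - w) + arr[e + 1L, j, k] * w
      }
    }
  }
  ans <- track
  ans@coords <- arr
  ans
}
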