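#' Build the per-frame kinematic feature matrix
#'
#' For every step frame i -> i+1 (the feature row of frame i), features are
#' the per-node speed in cm/s followed by the per-node x and y position in
#' centimetres relative to the arena origin (positions of frame i). Frames
#' with any missing feature are dropped, then every column is z-scored;
#' constant columns are set to 0 and flagged by a recorded scale of 0 so
#' the transform can be inverted.
#'
#' @param track a [PoseTrack-class] with at least 2 frames.
#' @param geometry an [ArenaGeometry-class].
#' @return a [FeatureMatrix-class].
#' @export
buildFeatures <- function(track, geometry) {
  if (nFrames(track) < 2L) stop("need at least 2 frames to build features")
  nn <- nodeNames(track)
  kin <- computeKinematics(track, geometry)
  speed <- nodeSpeed(kin)
  ppc <- pixelsPerCm(geometry)
  nf <- nFrames(track)
  xcm <- (track@coords[-nf, , 1, drop = FALSE][, , 1] - geometry@xMinPx) / ppc
  ycm <- (track@coords[-nf, , 2, drop = FALSE][, , 1] - geometry@yMinPx) / ppc
  xcm <- matrix(xcm, nf - 1L, length(nn))
  ycm <- matrix(ycm, nf - 1L, length(nn))
  pos <- matrix(NA_real_, nf - 1L, 2L * length(nn))
  pos[, seq(1L, by = 2L, length.out = length(nn))] <- xcm
  pos[, seq(2L, by = 2L, length.out = length(nn))] <- ycm
  raw <- cbind(speed, pos)
  colnames(raw) <- c(paste0("speed_", nn),
    as.vector(rbind(paste0(nn, "_x"), paste0(nn, "_y"))))
  keep <- stats::complete.cases(raw)
  if (sum(keep) < 2L) stop("fewer than 2 frames with complete features")
  raw <- raw[keep, , drop = FALSE]
  ctr <- colMeans(raw)
  sdev <- apply(raw, 2, stats::sd)
  sdev[!is.finite(sdev)] <- 0
  std <- sweep(raw, 2, ctr, "-")
  nz <- sdev > 0
  std[, nz] <- sweep(std[, nz, drop = FALSE], 2, sdev[nz], "/")
  std[, !nz] <- 0
  new("FeatureMatrix", mat = std, frames = which(keep) - 1L,
    center = ctr, scale = sdev, fps = track@fps, nodeNames = nn)
}

# invert the standardization back to physical units
unstandardize <- function(features) {
  m <- sweep(features@mat, 2, features@scale, "*")
  sweep(m, 2, features@center, "+")
}

#' Cluster frames into k behaviors with k-means
#'
#' By default the position block is rebalanced before clustering: the
#' x/y columns of a rigid body are mutually near-collinear, so under plain
#' per-column z-scoring the \code{2 n} position columns would outweigh the
#' \code{n} speed columns by raw column count while carrying only about two
#' dimensions of information (where the animal is). Balancing rescales the
#' position block so its total variance equals its effective rank
#' (participation ratio of its covariance eigenvalues), letting movement
#' — which defines behavior — and location contribute in proportion to the
#' information each holds. Set \code{balance = FALSE} to cluster the plain
#' z-scored features.
#'
#' @param features a [FeatureMatrix-class].
#' @param k number of clusters (default 4: resting, scurrying, left- and
#'   right-leg movement).
#' @param seed random seed; identical features + seed give identical labels.
#' @param nstart number of random restarts (best inertia kept).
#' @param balance rebalance the position block by effective rank
#'   (default TRUE).
#' @return integer vector of 0-based cluster ids, one per retained frame.
#' @export
clusterFrames <- function(features, k = 4L, seed = 42L, nstart = 50L,
                          balance = TRUE) {
  m <- featureMatrix(features)
  if (nrow(m) < k) stop("need at least k rows to form k clusters")
  if (nrow(m) == k) return(seq_len(k) - 1L)  # singleton clusters, zero inertia
  if (balance) {
    nSpeed <- length(features@nodeNames)
    posCols <- (nSpeed + 1L):ncol(m)
    pos <- m[, posCols, drop = FALSE]
    ev <- pmax(eigen(crossprod(pos) / nrow(pos), symmetric = TRUE,
      only.values = TRUE)$values, 0)
    if (sum(ev) > 0) {
      reff <- sum(ev)^2 / sum(ev^2)
      m[, posCols] <- pos * sqrt(reff / length(posCols))
    }
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(restoreSeed(old))
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 200L)
  as.integer(km$cluster - 1L)
}

#' Attach behavior names to 4 clusters
#'
#' Heuristic semantic labeling of a k = 4 clustering: the cluster with the
#' lowest mean body-node speed (in physical cm/s, midline nodes) is
#' resting; the highest is scurrying; the remaining two are split by the
#' sign of the mean left-minus-right leg-node speed (positive = left leg
#' movement). Exact ties are broken deterministically by cluster id and
#' flagged.
#'
#' @param labels 0-based cluster ids from [clusterFrames()].
#' @param features the [FeatureMatrix-class] the labels came from.
#' @param skeleton the [SkeletonDef-class] (for node sides).
#' @return named character vector mapping cluster id ("0".."3") to
#'   behavior, with attribute \code{tie} (logical).
#' @export
labelClusters <- function(labels, features, skeleton) {
  k <- length(unique(labels))
  if (length(setdiff(labels, 0:3)) || k != 4L) {
    stop("semantic labeling is defined for exactly 4 clusters; ",
      "keep raw cluster ids for other k")
  }
  raw <- unstandardize(features)
  nn <- features@nodeNames
  bodyCols <- paste0("speed_", nn[skeleton@limbSides[nn] == "midline"])
  leftCols <- paste0("speed_", legNodes(skeleton, "left"))
  rightCols <- paste0("speed_", legNodes(skeleton, "right"))
  bodyCols <- intersect(bodyCols, colnames(raw))
  ids <- 0:3
  bodySp <- vapply(ids, function(i) {
    mean(raw[labels == i, bodyCols, drop = FALSE])
  }, numeric(1))
  tie <- anyDuplicated(bodySp) > 0L
  map <- rep(NA_character_, 4)
  names(map) <- as.character(ids)
  rest <- ids[which.min(bodySp)]          # which.min/max break ties by id
  scur <- ids[which.max(bodySp)]
  if (rest == scur) scur <- setdiff(ids, rest)[1]
  map[as.character(rest)] <- "resting"
  map[as.character(scur)] <- "scurrying"
  rem <- setdiff(ids, c(rest, scur))
  lr <- vapply(rem, function(i) {
    rows <- labels == i
    mean(raw[rows, leftCols, drop = FALSE]) -
      mean(raw[rows, rightCols, drop = FALSE])
  }, numeric(1))
  if (lr[1] == lr[2]) tie <- TRUE
  leftFirst <- if (lr[1] != lr[2]) lr[1] > lr[2] else TRUE
  map[as.character(rem[1])] <- if (leftFirst) "left_leg" else "right_leg"
  map[as.character(rem[2])] <- if (leftFirst) "right_leg" else "left_leg"
  attr(map, "tie") <- tie
  map
}

#' Embed features in 2-D (PCA or UMAP)
#'
#' PCA projects onto the leading principal axes of the (already
#' standardized) features and is deterministic up to axis sign. UMAP uses
#' the study-style hyperparameters carried by \code{params} with a fixed
#' seed and a single thread, so repeated runs agree.
#'
#' @param features a [FeatureMatrix-class].
#' @param params an [EmbeddingParams-class].
#' @return numeric matrix with one row per retained frame and
#'   \code{params@nComponents} columns.
#' @export
embed2d <- function(features, params = EmbeddingParams()) {
  m <- featureMatrix(features)
  if (nrow(m) < params@nComponents + 1L) {
    stop("too few rows for a ", params@nComponents, "-component embedding")
  }
  if (params@method == "pca") {
    pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
    emb <- pc$x[, seq_len(params@nComponents), drop = FALSE]
  } else {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(params@seed)
    on.exit(restoreSeed(old))
    emb <- uwot::umap(m,
      n_neighbors = min(params@nNeighbors, nrow(m) - 1L),
      n_components = params@nComponents,
      min_dist = params@minDist, spread = params@spread,
      metric = "euclidean", n_threads = 1, n_sgd_threads = 0)
  }
  dimnames(emb) <- list(NULL, paste0("dim", seq_len(ncol(emb))))
  emb
}

#' Segment frame labels into bouts and total time per behavior
#'
#' Maximal runs of a constant label become bouts (0-based, half-open over
#' the retained-frame rows); time per behavior is the label count divided
#' by fps.
#'
#' @param labels integer cluster ids (nonempty).
#' @param fps frames per second.
#' @param semanticMap optional map from [labelClusters()]; when given,
#'   bouts gain a \code{behavior} column and times are keyed by behavior.
#' @return list with \code{bouts} (data.frame \code{start}, \code{end},
#'   \code{label}[, \code{behavior}]) and \code{timePerBehavior} (named
#'   numeric seconds).
#' @export
summarizeBouts <- function(labels, fps, semanticMap = NULL) {
  if (!length(labels)) stop("labels must be nonempty")
  r <- rle(as.integer(labels))
  end <- cumsum(r$lengths)
  b <- data.frame(start = end - r$lengths, end = end, label = r$values)
  keys <- sort(unique(as.integer(labels)))
  secs <- vapply(keys, function(l) sum(labels == l) / fps, numeric(1))
  names(secs) <- as.character(keys)
  if (!is.null(semanticMap)) {
    b$behavior <- unname(semanticMap[as.character(b$label)])
    secs <- tapply(secs, unname(semanticMap[names(secs)]), sum)
    secs <- stats::setNames(as.numeric(secs), names(secs))
  }
  list(bouts = b, timePerBehavior = secs)
}

#' Run the full ethogramming stage on one track
#'
#' Builds features, clusters them into \code{k} behaviors, attaches
#' semantic names (when \code{k} = 4), embeds the frames in 2-D and
#' segments bouts.
#'
#' @param track a [PoseTrack-class].
#' @param geometry an [ArenaGeometry-class].
#' @param k number of clusters (default 4).
#' @param seed clustering seed (default 42).
#' @param params [EmbeddingParams-class] for the embedding.
#' @param embed compute the 2-D embedding (default TRUE).
#' @param semantic attach behavior names (default TRUE when k = 4).
#' @return an [EthogramResult-class].
#' @export
runEthogram <- function(track, geometry, k = 4L, seed = 42L,
                        params = EmbeddingParams(), embed = TRUE,
                        semantic = (k == 4L)) {
  feats <- buildFeatures(track, geometry)
  labels <- clusterFrames(feats, k = k, seed = seed)
  map <- character()
  tie <- FALSE
  if (semantic) {
    map <- labelClusters(labels, feats, skeleton(track))
    tie <- isTRUE(attr(map, "tie"))
    attr(map, "tie") <- NULL
  }
  sm <- if (length(map)) map else NULL
  bt <- summarizeBouts(labels, feats@fps, sm)
  emb <- if (embed) embed2d(feats, params) else matrix(numeric(), 0, 0)
  new("EthogramResult", labels = labels, k = as.integer(k),
    semanticMap = if (length(map)) map else character(),
    bouts = bt$bouts, timePerBehavior = bt$timePerBehavior,
    embedding = emb, frames = retainedFrames(feats),
    seed = as.integer(seed), tie = tie)
}
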