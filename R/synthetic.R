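#' Simulate one linear-track session with ground truth
#'
#' Behavior states follow a first-order 4-state Markov chain
#' (resting, scurrying, left-leg movement, right-leg movement) with
#' state-conditioned Gaussian body speed. The body centroid moves along
#' the track's long axis with a persistent heading that is occasionally
#' resampled — biased toward the port zone with probability
#' \code{(1 + portBias) / 2} — and reflects at the walls; node positions
#' follow a rigid body template around the centroid, with sinusoidal leg
#' oscillation on the active side during leg-movement states. The session
#' starts in zone 1. The observed track is the truth plus Gaussian pixel
#' noise and independent per-node-frame dropout; ground-truth occupancy is
#' computed from the noiseless head trajectory and ground-truth states are
#' the chain itself. All randomness derives from \code{config@seed}.
#'
#' @param config a [SessionConfig-class].
#' @param group exposure group label carried by the dataset (default
#'   \code{"air"}).
#' @param videoID session identifier; default derived from group and seed.
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- generateSession(SessionConfig(durationS = 5, fps = 30, seed = 7))
#' secondsPerZone(scoreOccupancy(poseTrack(ds), ArenaGeometry()))
#' @export
generateSession <- function(config, group = "air", videoID = NULL) {
  validObject(config)
  if (is.null(videoID)) videoID <- sprintf("%s_seed%d", group, config@seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(config@seed)
  on.exit(restoreSeed(old))

  fps <- config@fps
  nf <- as.integer(round(config@durationS * fps))
  arena <- config@arena
  skel <- config@skeleton
  reg <- config@regimes
  L <- arena@lengthCm
  W <- arena@widthCm

  stateNames <- reg$state
  states <- integer(nf)
  states[1] <- 1L  # sessions begin at rest in zone 1
  u <- stats::runif(nf)
  pick <- matrix(stats::runif(2L * nf), nf, 2L)
  for (t in 2:nf) {
    s <- states[t - 1L]
    if (u[t] < reg$dwell[s]) {
      states[t] <- s
    } else {
      others <- (1:4)[-s]
      states[t] <- others[1L + floor(pick[t, 1L] * 3)]
    }
  }

  speed <- pmax(0, stats::rnorm(nf, reg$bodyMean[states], reg$bodySd[states]))
  pTowardPort <- (1 + config@portBias) / 2
  # heading is resampled at ~0.15 events/s (fps-invariant): locomotion is
  # a sequence of directed runs, as in dash-and-rest exploration
  flip <- stats::runif(nf) < 0.15 / fps
  towards <- pick[, 2L] < pTowardPort

  x <- numeric(nf)
  x[1] <- L / (2 * arena@nZones)  # centre of zone 1
  h <- 1
  scurry <- which(reg$state == "scurrying")
  for (t in 2:nf) {
    # every dash (entry into scurrying) picks a direction under the port
    # bias, as do the rarer mid-run changes of heart
    newDash <- states[t] == scurry && states[t - 1L] != scurry
    if (flip[t] || newDash) h <- if (towards[t]) 1 else -1
    # drift toward/away from the port rides on the state's own speed, so
    # at portBias -1 approach stalls while retreat doubles, and resting
    # frames stay essentially still
    xn <- x[t - 1L] + (h + config@portBias) * speed[t] / fps
    if (xn < 0) { xn <- -xn; h <- 1 }
    if (xn > L) { xn <- 2 * L - xn; h <- -1 }
    x[t] <- min(max(xn, 0), L)
  }
  # cross-axis wander scales with the state's own speed so a resting
  # animal is genuinely still
  yinn <- stats::rnorm(nf, 0, 0.15 * speed / fps)
  y <- stats::filter(yinn, 0.995, method = "recursive")
  y <- W / 2 + pmin(pmax(as.numeric(y), -W / 2 + 0.5), W / 2 - 0.5)

  off <- skeletonTemplate(skel)
  nn <- skel@nodeNames
  truthCm <- array(NA_real_, c(nf, length(nn), 2))
  truthCm[, , 1] <- outer(x, off[, 1], "+")
  truthCm[, , 2] <- outer(y, off[, 2], "+")

  # active legs cycle along a small circle (stepping ellipse), so the limb
  # speed is steady within a bout rather than pulsing through zero
  tvec <- (seq_len(nf) - 1L) / fps
  legFreq <- 5  # Hz leg cycling during lateralized movement
  for (side in c("left", "right")) {
    legs <- match(legNodes(skel, side), nn)
    act <- reg$limbSide[states] == side | reg$limbSide[states] == "both"
    if (!any(act) || !length(legs)) next
    amp <- reg$limbAmp[states]
    for (jj in seq_along(legs)) {
      ph <- 2 * pi * jj / length(legs)
      w <- 2 * pi * legFreq * tvec + ph
      truthCm[, legs[jj], 1] <- truthCm[, legs[jj], 1] + amp * cos(w) * act
      truthCm[, legs[jj], 2] <- truthCm[, legs[jj], 2] + amp * sin(w) * act
    }
  }

  ppc <- pixelsPerCm(arena)
  truthPx <- truthCm
  truthPx[, , 1] <- arena@xMinPx + truthCm[, , 1] * ppc
  truthPx[, , 2] <- arena@yMinPx + truthCm[, , 2] * ppc

  headX <- truthPx[, match(skel@anchorHead, nn), 1]
  occ <- truthOccupancyFromHead(headX, fps, arena)

  obs <- truthPx
  if (config@noiseSdPx > 0) {
    obs <- obs + array(stats::rnorm(length(obs), 0, config@noiseSdPx), dim(obs))
  }
  if (config@missingRate > 0) {
    drop <- matrix(stats::runif(nf * length(nn)) < config@missingRate,
                   nf, length(nn))
    obs[, , 1][drop] <- NA_real_
    obs[, , 2][drop] <- NA_real_
  }

  track <- PoseTrack(obs, skeleton = skel, fps = fps, videoID = videoID)
  new("SyntheticDataset", track = track, truthOccupancy = occ,
    truthStates = stateNames[states], group = group, config = config)
}

# Per-second majority zone of the (noiseless) head x trajectory; same
# scoring convention as scoreOccupancy but computed directly here so the
# pipeline check compares two code paths.
truthOccupancyFromHead <- function(headXpx, fps, arena) {
  nSec <- floor(length(headXpx) / fps)
  br <- seq(arena@xMinPx, arena@xMaxPx, length.out = arena@nZones + 1L)
  z <- pmin(pmax(findInterval(headXpx, br), 1L), arena@nZones)
  occ <- integer(nSec)
  prev <- NA_integer_
  for (s in seq_len(nSec)) {
    zs <- z[(floor((s - 1) * fps) + 1L):floor(s * fps)]
    counts <- tabulate(zs, nbins = arena@nZones)
    cand <- which(counts == max(counts))
    occ[s] <- if (!is.na(prev) && prev %in% cand) prev else min(cand)
    prev <- occ[s]
  }
  occ
}

#' Simulate a full cohort (groups x animals x days)
#'
#' One dataset per animal and day, with per-session seeds derived
#' deterministically (and collision-free) from the base seed and each
#' group's port bias taken from \code{groupEffects}.
#'
#' @param base a [SessionConfig-class] used as the template; its
#'   \code{portBias} is overridden per group and its \code{seed} anchors
#'   the seed schedule.
#' @param nPerGroup animals per group (default 6).
#' @param groupEffects named numeric of port biases per group; default
#'   \code{c(air = 0, vehicle = -0.6, nicotine = 0.2)}.
#' @param days sessions per animal (default 14).
#' @return list of [SyntheticDataset-class] objects with a \code{manifest}
#'   attribute (data.frame: id, group, animal, day, seed).
#' @export
generateCohort <- function(base, nPerGroup = 6L,
                           groupEffects = c(air = 0, vehicle = -0.6,
                                            nicotine = 0.2),
                           days = 14L) {
  stopifnot(nPerGroup >= 1L, days >= 1L)
  groups <- names(groupEffects)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("groupEffects must be named by group")
  }
  out <- vector("list", length(groups) * nPerGroup * days)
  man <- vector("list", length(out))
  idx <- 0L
  for (gi in seq_along(groups)) {
    for (a in seq_len(nPerGroup)) {
      for (d in seq_len(days)) {
        idx <- idx + 1L
        seed <- (base@seed %% 10007L) * 200003L + idx
        cfg <- base
        cfg@portBias <- unname(groupEffects[gi])
        cfg@seed <- as.integer(seed)
        id <- sprintf("%s_a%02d_d%02d", groups[gi], a, d)
        out[[idx]] <- generateSession(cfg, group = groups[gi], videoID = id)
        man[[idx]] <- data.frame(id = id, group = groups[gi], animal = a,
          day = d, seed = seed)
      }
    }
  }
  attr(out, "manifest") <- do.call(rbind, man)
  out
}

#' Corrupt a pose track with detection noise and dropout
#'
#' Adds Gaussian pixel noise to every present coordinate and drops
#' node-frames independently; any ground truth attached to the session is
#' untouched. With zero rates the track is returned bit-identical.
#'
#' @param track a [PoseTrack-class].
#' @param missingRate per-node-frame dropout probability in \code{[0, 1)}.
#' @param noiseSdPx Gaussian noise sd, pixels.
#' @param seed integer seed.
#' @return a corrupted [PoseTrack-class].
#' @export
corrupt <- function(track, missingRate = 0, noiseSdPx = 0, seed = 1L) {
  stopifnot(missingRate >= 0, missingRate < 1, noiseSdPx >= 0)
  if (missingRate == 0 && noiseSdPx == 0) return(track)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(restoreSeed(old))
  arr <- track@coords
  nf <- dim(arr)[1]; nNode <- dim(arr)[2]
  if (noiseSdPx > 0 && nf > 0) {
    noise <- array(stats::rnorm(length(arr), 0, noiseSdPx), dim(arr))
    arr <- arr + noise
  }
  if (missingRate > 0 && nf > 0) {
    drop <- matrix(stats::runif(nf * nNode) < missingRate, nf, nNode)
    arr[, , 1][drop] <- NA_real_
    arr[, , 2][drop] <- NA_real_
  }
  ans <- track
  ans@coords <- arr
  ans
}

#' Write a synthetic dataset to disk
#'
#' The pose track goes to a SLEAP-style HDF5 file and the ground truth to
#' a JSON sidecar (\code{<id>.truth.json} with occupancy, states, group).
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return named character of the two paths, invisibly.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- videoID(poseTrack(ds))
  h5 <- file.path(dir, paste0(id, ".h5"))
  js <- file.path(dir, paste0(id, ".truth.json"))
  writePoseH5(poseTrack(ds), h5)
  jsonlite::write_json(list(group = groupLabel(ds),
    truth_occupancy = truthOccupancy(ds), truth_states = truthStates(ds)),
    js, auto_unbox = TRUE)
  invisible(c(track = h5, truth = js))
}

#' Write a cohort to disk with a manifest
#'
#' @param datasets output of [generateCohort()].
#' @param dir output directory.
#' @return path of the manifest CSV (columns id, group, animal, day, seed,
#'   track_path, truth_path), invisibly.
#' @export
writeCohort <- function(datasets, dir) {
  man <- attr(datasets, "manifest")
  stopifnot(!is.null(man))
  paths <- lapply(datasets, writeSyntheticDataset, dir = dir)
  man$track_path <- vapply(paths, `[[`, "", "track")
  man$truth_path <- vapply(paths, `[[`, "", "truth")
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
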