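# Independent oracles and tiny fixtures shared across tests.

# all permutations of a vector (n <= 4 here)
permn <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in permn(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# best frame agreement between cluster labels and truth over all
# cluster -> state bijections (brute-force alignment)
bestAlignment <- function(labels, truth) {
  states <- sort(unique(truth))
  ids <- sort(unique(labels))
  best <- 0
  for (p in permn(states)) {
    m <- stats::setNames(p[seq_along(ids)], as.character(ids))
    best <- max(best, mean(m[as.character(labels)] == truth))
  }
  best
}

# exhaustive-permutation two-sided Mann-Whitney p (tie-free data):
# enumerate every assignment of the pooled values to group A
mwPermOracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  uOf <- function(av, bv) sum(outer(av, bv, ">")) # no ties by construction
  us <- apply(idx, 2, function(i) uOf(pool[i], pool[-i]))
  u <- uOf(a, b)
  pLess <- mean(us <= u)
  pMore <- mean(us >= u)
  list(u = u, p = min(1, 2 * min(pLess, pMore)))
}

# Benjamini-Hochberg step-up from its definition
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, po[i] * m / i)
    adj[i] <- cur
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# one-node skeleton and a track following a given pixel path
oneNodeSkeleton <- function() {
  SkeletonDef("head", anchorHead = "head", anchorBody = "head")
}

pathTrack <- function(x, y = rep(50, length(x)), fps = 10, skel = oneNodeSkeleton()) {
  arr <- array(NA_real_, c(length(x), length(nodeNames(skel)), 2))
  y[is.na(x)] <- NA
  arr[, 1, 1] <- x
  arr[, 1, 2] <- y
  PoseTrack(arr, skeleton = skel, fps = fps, videoID = "toy")
}

# small random multi-node track with optional missing entries
randomTrack <- function(nf = 20, skel = cockroachSkeleton(), fps = 30,
                        missFrac = 0.1, seed = 1) {
  set.seed(seed)
  nn <- length(nodeNames(skel))
  arr <- array(stats::runif(nf * nn * 2, 0, 1200), c(nf, nn, 2))
  if (missFrac > 0 && nf > 0) {
    drop <- matrix(stats::runif(nf * nn) < missFrac, nf, nn)
    arr[, , 1][drop] <- NA_real_
    arr[, , 2][drop] <- NA_real_
  }
  PoseTrack(arr, skeleton = skel, fps = fps, videoID = paste0("rand", seed))
}

# FeatureMatrix wrapper for hand-built matrices (2 "nodes" -> 6 columns)
toyFeatures <- function(mat, fps = 30) {
  stopifnot(ncol(mat) == 6)
  colnames(mat) <- c("speed_a", "speed_b", "a_x", "a_y", "b_x", "b_y")
  new("FeatureMatrix", mat = mat, frames = seq_len(nrow(mat)) - 1L,
    center = rep(0, 6), scale = rep(1, 6), fps = fps,
    nodeNames = c("a", "b"))
}

defaultSessionConfig <- function(seed, ...) {
  SessionConfig(durationS = 120, fps = 30, seed = seed, ...)
}

semanticAgreement <- function(ds, geometry = ArenaGeometry()) {
  eth <- runEthogram(poseTrack(ds), geometry, embed = FALSE)
  sem <- unname(semanticMap(eth)[as.character(frameLabels(eth))])
  truth <- truthStates(ds)[retainedFrames(eth) + 1L]
  mean(sem == truth)
}
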