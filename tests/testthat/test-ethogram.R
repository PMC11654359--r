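test_that("features are z-scored with the transform recorded", {
  sk <- SkeletonDef(c("a", "b"), "a", "b")
  arr <- array(rep(c(100, 120), each = 10), c(10, 2, 2))
  tr <- PoseTrack(arr, sk, fps = 30)
  g <- ArenaGeometry()
  f <- buildFeatures(tr, g)
  # stationary track: all speed columns are 0 before standardization
  raw <- sweep(sweep(featureMatrix(f), 2, f@scale, "*"), 2, f@center, "+")
  expect_true(all(raw[, 1:2] == 0))
  m <- featureMatrix(f)
  expect_true(all(abs(colMeans(m)) < 1e-9))
  sds <- apply(m, 2, sd)
  expect_true(all(abs(sds) < 1e-9 | abs(sds - 1) < 1e-9))
})

test_that("frames with any missing node are dropped from the features", {
  tr <- randomTrack(nf = 30, missFrac = 0, seed = 3)
  arr <- poseCoords(tr)
  arr[5, 2, ] <- NA
  tr <- PoseTrack(arr, skeleton(tr), fps = framesPerSecond(tr))
  f <- buildFeatures(tr, ArenaGeometry())
  # speed rows 4 and 5 (0-based) touch frame 5 (1-based); frame rows are
  # step-start frames, so 0-based frames 3 and 4 are gone
  expect_false(any(retainedFrames(f) %in% c(3L, 4L)))
  expect_equal(ncol(featureMatrix(f)), 3 * 27)
  expect_error(buildFeatures(pathTrack(5), ArenaGeometry()), "2 frames")
})

test_that("k-means separates well-separated blobs and is deterministic", {
  set.seed(10)
  blob <- rbind(matrix(rnorm(300, 0, 0.2), 50, 6),
                matrix(rnorm(300, 5, 0.2), 50, 6))
  f <- toyFeatures(blob)
  lab <- clusterFrames(f, k = 2, seed = 42, balance = FALSE)
  expect_equal(length(unique(lab[1:50])), 1)
  expect_equal(length(unique(lab[51:100])), 1)
  expect_false(lab[1] == lab[51])
  expect_identical(lab, clusterFrames(f, k = 2, seed = 42, balance = FALSE))
})

test_that("k equal to rows gives singleton clusters; fewer rows errors", {
  set.seed(11)
  f <- toyFeatures(matrix(rnorm(30), 5, 6))
  lab <- clusterFrames(f, k = 5, seed = 1)
  expect_equal(sort(unique(lab)), 0:4)
  expect_error(clusterFrames(f, k = 6), "at least k")
})

test_that("duplicate rows stay co-clustered (nearest-centroid oracle)", {
  set.seed(12)
  base <- matrix(rnorm(60, sd = 3), 10, 6)
  dup <- rbind(base, base)
  f <- toyFeatures(dup)
  lab <- clusterFrames(f, k = 3, seed = 7, balance = FALSE)
  expect_identical(lab[1:10], lab[11:20])
  # oracle: every row sits with its nearest final centroid
  cen <- sapply(0:2, function(i) colMeans(dup[lab == i, , drop = FALSE]))
  d2 <- as.matrix(dist(rbind(dup, t(cen))))[1:20, 21:23]
  expect_identical(max.col(-d2) - 1L, lab)
})

test_that("semantic labeling recovers the four regimes on synthetic data", {
  ds <- generateSession(defaultSessionConfig(seed = 11))
  g <- ArenaGeometry()
  f <- buildFeatures(poseTrack(ds), g)
  lab <- clusterFrames(f, k = 4, seed = 42)
  map <- labelClusters(lab, f, skeleton(poseTrack(ds)))
  expect_setequal(unname(map),
    c("resting", "scurrying", "left_leg", "right_leg"))
  sem <- unname(map[as.character(lab)])
  truth <- truthStates(ds)[retainedFrames(f) + 1L]
  expect_gte(mean(sem == truth), 0.9)
})

test_that("semantic labeling rejects k != 4 and flags exact ties", {
  f <- toyFeatures(matrix(rnorm(60), 10, 6))
  expect_error(labelClusters(rep(0:2, length.out = 10), f,
    cockroachSkeleton()), "4 clusters")
  # clusters 1 and 2 are identical rows -> identical summaries -> tie flag
  sk <- cockroachSkeleton()
  nn <- nodeNames(sk)
  m <- matrix(0, 40, 3 * 27)
  colnames(m) <- c(paste0("speed_", nn),
    as.vector(rbind(paste0(nn, "_x"), paste0(nn, "_y"))))
  m[1:10, 1:27] <- 0.01   # resting-ish
  m[11:20, 1:27] <- 5     # fast
  m[21:30, 1:27] <- 1
  m[31:40, 1:27] <- 1     # identical to previous cluster
  fm <- new("FeatureMatrix", mat = m, frames = 0:39,
    center = rep(0, ncol(m)), scale = rep(1, ncol(m)), fps = 30,
    nodeNames = nn)
  lab <- rep(0:3, each = 10)
  map <- labelClusters(lab, fm, sk)
  expect_true(attr(map, "tie"))
  expect_setequal(unname(map),
    c("resting", "scurrying", "left_leg", "right_leg"))
})

test_that("PCA embedding matches a direct eigendecomposition (oracle)", {
  set.seed(20)
  m <- matrix(rnorm(20), 5, 4)
  m <- scale(m)[, ]  # embed2d expects standardized input
  colnames(m) <- NULL
  fm <- new("FeatureMatrix", mat = cbind(m, m[, 1:2]), frames = 0:4,
    center = rep(0, 6), scale = rep(1, 6), fps = 30,
    nodeNames = c("a", "b"))
  emb <- embed2d(fm, EmbeddingParams(method = "pca"))
  ev <- eigen(stats::cov(featureMatrix(fm)))
  oracle <- featureMatrix(fm) %*% ev$vectors[, 1:2]
  expect_equal(abs(emb), abs(oracle), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gte(stats::var(emb[, 1]), stats::var(emb[, 2]))
})

test_that("PCA reconstructs exactly planar data", {
  set.seed(21)
  basis <- matrix(rnorm(12), 2, 6)
  coef2 <- matrix(rnorm(60), 30, 2)
  m <- coef2 %*% basis
  fm <- toyFeatures(m)
  emb <- embed2d(fm, EmbeddingParams(method = "pca"))
  # rank 2 data: the top-2 projection carries all the variance
  pc <- stats::prcomp(m, center = FALSE)
  expect_lt(sum(pc$sdev[-(1:2)]^2), 1e-20)
  expect_equal(sum(emb^2), sum(m^2), tolerance = 1e-8)
})

test_that("UMAP embedding is seeded, reproducible and the right shape", {
  set.seed(22)
  f <- toyFeatures(matrix(rnorm(50 * 6), 50, 6))
  p <- EmbeddingParams(method = "umap", nNeighbors = 10, seed = 42)
  e1 <- embed2d(f, p)
  e2 <- embed2d(f, p)
  expect_equal(dim(e1), c(50L, 2L))
  expect_identical(e1, e2)
  expect_error(embed2d(toyFeatures(matrix(rnorm(12), 2, 6)),
    EmbeddingParams(method = "pca", nComponents = 2)), "too few rows")
})

test_that("bout segmentation is run-length encoding with time conservation", {
  bt <- summarizeBouts(c(0L, 0L, 1L, 1L, 1L, 0L), fps = 2)
  expect_equal(bt$bouts$start, c(0L, 2L, 5L))
  expect_equal(bt$bouts$end, c(2L, 5L, 6L))
  expect_equal(bt$bouts$label, c(0L, 1L, 0L))
  expect_equal(sum(bt$timePerBehavior), 3)

  one <- summarizeBouts(rep(2L, 7), fps = 7)
  expect_equal(nrow(one$bouts), 1)
  expect_equal(unname(one$timePerBehavior), 1)

  set.seed(30)
  for (i in 1:3) {
    lab <- sample(0:3, 50, replace = TRUE)
    bt <- summarizeBouts(lab, fps = 30)
    expect_equal(sum(bt$timePerBehavior), 50 / 30)
    expect_equal(sum(bt$bouts$end - bt$bouts$start), 50)
  }
  expect_error(summarizeBouts(integer(), 30), "nonempty")
})

test_that("the full ethogram stage is deterministic under a fixed seed", {
  ds <- generateSession(SessionConfig(durationS = 20, fps = 30, seed = 8))
  g <- ArenaGeometry()
  e1 <- runEthogram(poseTrack(ds), g, seed = 42)
  e2 <- runEthogram(poseTrack(ds), g, seed = 42)
  expect_identical(frameLabels(e1), frameLabels(e2))
  expect_identical(semanticMap(e1), semanticMap(e2))
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
  expect_equal(sum(timePerBehavior(e1)), length(frameLabels(e1)) / 30)
})
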