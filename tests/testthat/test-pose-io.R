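test_that("HDF5 write/read round trip preserves coordinates and missingness", {
  for (seed in 1:4) {
    tr <- randomTrack(nf = 15, fps = c(30, 60, 24, 50)[seed],
      missFrac = c(0, 0.1, 0.3, 0.05)[seed], seed = seed)
    f <- withr::local_tempfile(fileext = ".h5")
    writePoseH5(tr, f)
    tr2 <- readPoseH5(f)
    expect_identical(poseCoords(tr2), poseCoords(tr))
    expect_equal(framesPerSecond(tr2), framesPerSecond(tr))
    expect_identical(nodeNames(tr2), nodeNames(tr))
  }
})

test_that("round trip keeps an all-missing node and an empty track", {
  sk <- cockroachSkeleton()
  arr <- array(1, c(4, 27, 2))
  arr[, 7, ] <- NA
  tr <- PoseTrack(arr, sk, fps = 60)
  f <- withr::local_tempfile(fileext = ".h5")
  writePoseH5(tr, f)
  expect_true(all(is.na(poseCoords(readPoseH5(f))[, 7, ])))

  e <- PoseTrack(array(numeric(), c(0, 27, 2)), sk, fps = 60)
  f2 <- withr::local_tempfile(fileext = ".h5")
  writePoseH5(e, f2)
  expect_equal(nFrames(readPoseH5(f2)), 0)
})

test_that("a 27-node, 3600-frame session file reads with the full skeleton", {
  tr <- randomTrack(nf = 3600, fps = 30, missFrac = 0, seed = 5)
  f <- withr::local_tempfile(fileext = ".h5")
  writePoseH5(tr, f)
  got <- readPoseH5(f)
  expect_equal(nNodes(got), 27)
  expect_equal(nFrames(got), 3600)
})

test_that("malformed files and skeleton mismatches raise informative errors", {
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5write(array(1, c(3, 2, 2, 1)), f, "tracks")  # no node_names
  rhdf5::H5close()
  expect_error(readPoseH5(f), "node_names")

  tr <- randomTrack(nf = 3, seed = 2)
  f2 <- withr::local_tempfile(fileext = ".h5")
  writePoseH5(tr, f2)
  small <- SkeletonDef(c("a", "b"), "a", "b")
  expect_error(readPoseH5(f2, skeletonOverride = small), "2 nodes")
  expect_error(readPoseH5(file.path(tempdir(), "nope.h5")), "not found")
})

test_that("fps falls back to the caller default when the file has none", {
  tr <- randomTrack(nf = 3, seed = 3)
  f <- withr::local_tempfile(fileext = ".h5")
  writePoseH5(tr, f)
  # strip the rate metadata
  f2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f2)
  rhdf5::h5write(rhdf5::h5read(f, "tracks"), f2, "tracks")
  rhdf5::h5write(rhdf5::h5read(f, "node_names"), f2, "node_names")
  rhdf5::H5close()
  expect_equal(framesPerSecond(readPoseH5(f2)), 60)
  expect_equal(framesPerSecond(readPoseH5(f2, defaultFps = 24)), 24)
})

test_that("datasheet export has the documented shape and survives re-import", {
  sk <- SkeletonDef(c("a", "b"), "a", "b")
  arr <- array(c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5), c(2, 2, 2))
  tr <- PoseTrack(arr, sk, fps = 40, videoID = "v")
  f <- withr::local_tempfile(fileext = ".csv")
  exportDatasheet(tr, f)
  df <- read.csv(f)
  expect_equal(dim(df), c(2L, 7L))
  expect_equal(df$time_s, df$frame / 40)

  tr2 <- randomTrack(nf = 12, missFrac = 0.2, seed = 9)
  f2 <- withr::local_tempfile(fileext = ".csv")
  exportDatasheet(tr2, f2)
  back <- readDatasheet(f2)
  expect_equal(poseCoords(back), poseCoords(tr2), tolerance = 1e-9)
  expect_identical(is.na(poseCoords(back)), is.na(poseCoords(tr2)))
  expect_equal(framesPerSecond(back), framesPerSecond(tr2))
})

test_that("fillMissing interpolates short interior gaps only", {
  sk <- oneNodeSkeleton()
  x <- c(0, NA, 2, 10, NA, NA, NA, NA, NA, 20, NA)
  tr <- pathTrack(x)
  filled <- fillMissing(tr, 1)
  expect_equal(poseCoords(filled)[2, 1, 1], 1)       # midpoint
  expect_true(all(is.na(poseCoords(filled)[5:9, 1, 1])))  # gap of 5 > 1
  expect_true(is.na(poseCoords(filled)[11, 1, 1]))   # trailing stays
  expect_identical(poseCoords(fillMissing(tr, 0)), poseCoords(tr))
  wide <- fillMissing(tr, 5)
  expect_equal(poseCoords(wide)[5:9, 1, 1], 10 + (1:5) / 6 * 10,
    tolerance = 1e-12)
})

test_that("fillMissing is idempotent and never edits present values", {
  for (seed in 1:3) {
    tr <- randomTrack(nf = 40, missFrac = 0.3, seed = seed)
    once <- fillMissing(tr, 3)
    twice <- fillMissing(once, 3)
    expect_identical(poseCoords(once), poseCoords(twice))
    pres <- !is.na(poseCoords(tr))
    expect_identical(poseCoords(once)[pres], poseCoords(tr)[pres])
  }
})

test_that("PoseTrack validity enforces paired missingness and finiteness", {
  sk <- oneNodeSkeleton()
  arr <- array(1, c(2, 1, 2))
  arr[1, 1, 1] <- NA  # x missing, y present
  expect_error(PoseTrack(arr, sk), "missing together")
  arr2 <- array(1, c(2, 1, 2))
  arr2[1, 1, 1] <- Inf
  expect_error(PoseTrack(arr2, sk), "finite")
  expect_error(SkeletonDef(c("a", "a"), "a", "a"), "unique")
  expect_error(SkeletonDef(c("a", "b"), "z", "b"), "anchorHead")
})
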