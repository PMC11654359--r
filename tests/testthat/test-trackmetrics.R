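geom400 <- ArenaGeometry(xMinPx = 0, xMaxPx = 400, yMinPx = 0, yMaxPx = 80,
  lengthCm = 40, widthCm = 8)

test_that("assignZone uses half-open intervals and clamps outside the runway", {
  expect_equal(assignZone(c(50, 100, 399.9, 405, -3, 0, 300), geom400),
    c(1L, 2L, 4L, 4L, 1L, 1L, 4L))
  expect_error(assignZone(NaN, geom400), "finite")
  expect_error(assignZone(Inf, geom400), "finite")
})

test_that("assignZone is total and single-valued on finite input", {
  set.seed(7)
  x <- runif(500, -100, 500)
  z <- assignZone(x, geom400)
  expect_true(all(z >= 1L & z <= 4L))
  expect_equal(length(z), 500)
})

test_that("occupancy of constant and step tracks matches the scoring rule", {
  fps <- 5
  cons <- pathTrack(rep(50, 120 * fps), fps = fps)
  occ <- scoreOccupancy(cons, geom400)
  expect_equal(unname(secondsPerZone(occ)), c(120, 0, 0, 0))

  step <- pathTrack(c(rep(50, 60 * fps), rep(350, 60 * fps)), fps = fps)
  occ2 <- scoreOccupancy(step, geom400)
  expect_equal(unname(secondsPerZone(occ2)), c(60, 0, 0, 60))
})

test_that("a second with no anchor detection is unscorable but conserved", {
  fps <- 4
  x <- rep(50, 10 * fps)
  x[(7 * fps + 1):(8 * fps)] <- NA  # second 7 (0-based) fully missing
  occ <- scoreOccupancy(pathTrack(x, fps = fps), geom400)
  expect_true(is.na(perSecond(occ)[8]))
  expect_equal(sum(secondsPerZone(occ)) + sum(is.na(perSecond(occ))),
    durationS(occ))
  expect_error(scoreOccupancy(pathTrack(x, fps = fps), geom400,
    anchor = "nope"), "anchor")
})

test_that("majority vote ties fall back to the previous second then low zone", {
  fps <- 4
  # second 0 fully in zone 2; second 1 split 2/2 between zones 2 and 3
  x <- c(rep(150, 4), 150, 150, 250, 250)
  occ <- scoreOccupancy(pathTrack(x, fps = fps), geom400)
  expect_equal(perSecond(occ), c(2L, 2L))
  # no previous label: split second -> lower zone index
  x2 <- c(150, 150, 250, 250)
  expect_equal(perSecond(scoreOccupancy(pathTrack(x2, fps = fps), geom400)), 2L)
})

test_that("occupancy conservation holds on random noisy tracks", {
  for (seed in 1:5) {
    tr <- randomTrack(nf = 95, fps = 10, missFrac = 0.4, seed = seed)
    g <- ArenaGeometry()
    occ <- scoreOccupancy(tr, g)
    expect_equal(sum(secondsPerZone(occ)) + sum(is.na(perSecond(occ))),
      durationS(occ))
  }
})

test_that("speeds follow the pixel-to-cm arithmetic", {
  # +1 px per frame, fps 60, 10 px/cm -> 6 cm/s at every step
  g <- ArenaGeometry(xMinPx = 0, xMaxPx = 400, lengthCm = 40,
    yMinPx = 0, yMaxPx = 80)  # 10 px/cm
  tr <- pathTrack(seq(0, 99), y = rep(40, 100), fps = 60)
  kin <- computeKinematics(tr, g)
  expect_equal(unname(nodeSpeed(kin)[, 1]), rep(6, 99))

  still <- pathTrack(rep(200, 50), fps = 60)
  kin0 <- computeKinematics(still, g)
  expect_true(all(nodeSpeed(kin0) == 0))
  expect_equal(totalDistanceCm(kin0), 0)
})

test_that("distance accumulates into the starting frame's zone", {
  g <- ArenaGeometry(xMinPx = 0, xMaxPx = 400, lengthCm = 40,
    yMinPx = 0, yMaxPx = 80)  # zone 2 = [100, 200)
  tr <- pathTrack(seq(110, 190, length.out = 31), fps = 10)  # 80 px = 8 cm? no: 300px path
  kin <- computeKinematics(tr, g)
  expect_equal(unname(distancePerZone(kin)),
    c(0, (190 - 110) / 10, 0, 0), tolerance = 1e-9)
  expect_equal(totalDistanceCm(kin), sum(distancePerZone(kin)),
    tolerance = 1e-12)
})

test_that("speeds are translation-invariant and scale with the calibration", {
  tr <- randomTrack(nf = 30, missFrac = 0, seed = 4)
  g <- ArenaGeometry()
  base <- computeKinematics(tr, g)
  shifted <- tr
  arr <- poseCoords(tr)
  arr[, , 1] <- arr[, , 1] + 37.5
  arr[, , 2] <- arr[, , 2] - 12.25
  shifted <- PoseTrack(arr, skeleton(tr), fps = framesPerSecond(tr))
  expect_equal(nodeSpeed(computeKinematics(shifted, g)), nodeSpeed(base),
    tolerance = 1e-9)
  gHalf <- ArenaGeometry(xMaxPx = ArenaGeometry()@xMaxPx,
    lengthCm = ArenaGeometry()@lengthCm * 2)  # half the px/cm
  expect_equal(nodeSpeed(computeKinematics(tr, gHalf)), nodeSpeed(base) * 2,
    tolerance = 1e-9)
})

test_that("path distance dominates net displacement", {
  for (seed in 1:5) {
    tr <- randomTrack(nf = 40, missFrac = 0, seed = seed)
    g <- ArenaGeometry()
    kin <- computeKinematics(tr, g)
    j <- match(anchorBody(skeleton(tr)), nodeNames(tr))
    net <- sqrt(sum((poseCoords(tr)[40, j, ] - poseCoords(tr)[1, j, ])^2)) /
      pixelsPerCm(g)
    expect_gte(totalDistanceCm(kin) + 1e-9, net)
  }
})

test_that("heat map conserves present-frame counts", {
  g <- ArenaGeometry()
  cons <- pathTrack(rep(600, 25), y = rep(100, 25), fps = 10)
  hm <- occupancyHeatmap(cons, g, node = "head", binsX = 12, binsY = 4)
  expect_equal(sum(hm), 25)
  expect_equal(sum(hm > 0), 1)

  for (seed in 1:3) {
    tr <- randomTrack(nf = 60, missFrac = 0.25, seed = seed)
    hm <- occupancyHeatmap(tr, g, node = "metathorax", binsX = 10, binsY = 5)
    expect_equal(sum(hm), sum(!is.na(poseCoords(tr)[, "metathorax", 1])))
  }
})

test_that("a uniform x sweep spreads evenly across columns (binning oracle)", {
  g <- ArenaGeometry(xMinPx = 0, xMaxPx = 400, yMinPx = 0, yMaxPx = 80,
    lengthCm = 40, widthCm = 8)
  n <- 400
  x <- seq(0, 399.999, length.out = n)
  tr <- pathTrack(x, y = rep(40, n), fps = 10)
  binsX <- 16
  hm <- occupancyHeatmap(tr, g, node = "head", binsX = binsX, binsY = 3)
  colCounts <- colSums(hm)
  # brute-force binning of the same sweep
  br <- seq(0, 400, length.out = binsX + 1)
  oracle <- tabulate(pmin(pmax(findInterval(x, br, rightmost.closed = TRUE),
    1L), binsX), binsX)
  expect_equal(unname(colCounts), oracle)
  expect_lte(max(colCounts) - min(colCounts), 1)
})
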