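test_that("Mann-Whitney matches the exhaustive-permutation oracle (n <= 4)", {
  expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6)),
    list(statistic = 0, p.value = 0.1))
  set.seed(40)
  for (na in 1:4) {
    for (nb in 1:4) {
      a <- round(rnorm(na), 6)
      b <- round(rnorm(nb) + 0.5, 6)
      got <- mannWhitney(a, b)
      want <- mwPermOracle(a, b)
      expect_equal(got$statistic, want$u)
      expect_equal(got$p.value, want$p, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney symmetry: swapping samples reflects U, keeps p", {
  set.seed(41)
  a <- rnorm(5); b <- rnorm(7)
  ab <- mannWhitney(a, b)
  ba <- mannWhitney(b, a)
  expect_equal(ab$statistic + ba$statistic, 5 * 7)
  expect_equal(ab$p.value, ba$p.value)
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p.value, 0.99)
})

test_that("BH adjustment equals the step-up oracle over a grid (m <= 6)", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 4)), rep(1, 4))
  set.seed(42)
  grid <- c(list(c(0.001, 0.5), c(0.04, 0.05, 0.06), c(0.5, 0.01, 0.9, 0.02)),
    lapply(1:6, function(m) round(runif(m), 4)))
  for (p in grid) {
    expect_equal(bhAdjust(p), bhStepUp(p), tolerance = 1e-12)
    expect_true(all(bhAdjust(p) >= p - 1e-12))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("identical groups yield a null omnibus and no pairwise hits", {
  rep3 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  cr <- gatedCompare(rep3)
  expect_gte(cr@omnibus$p.value, 0.99)
  expect_true(all(cr@pairwise$p.adj > 0.9))
  expect_true(all(cr@pairwise$p.adj >= cr@pairwise$p - 1e-12))
})

test_that("the gate branches sensibly for normal and skewed data", {
  # under exact normality each of the four alpha-0.05 gates can trip, so
  # the expected all-pass rate is ~0.95^4 ~ 0.81; require a clear majority
  set.seed(43)
  par <- mean(replicate(60, {
    gatedCompare(list(a = rnorm(20), b = rnorm(20), c = rnorm(20)))@branch ==
      "parametric"
  }))
  expect_gte(par, 0.7)
  set.seed(44)
  np <- mean(replicate(30, {
    gatedCompare(list(a = rexp(20), b = rexp(20), c = rexp(20)))@branch ==
      "nonparametric"
  }))
  expect_gte(np, 0.9)
  expect_error(gatedCompare(list(a = 1:2, b = 1:5, c = 1:5)), "n >= 3")
})

test_that("branch contents match the decision tree", {
  set.seed(45)
  skewed <- list(a = rexp(12), b = rexp(12) + 2, c = rexp(12))
  cr <- gatedCompare(skewed)
  expect_equal(cr@branch, "nonparametric")
  expect_equal(cr@omnibus$method, "Kruskal-Wallis")
  expect_true(all(cr@pairwise$method == "Mann-Whitney"))
  expect_equal(nrow(cr@pairwise), 3)

  set.seed(46)
  norm <- list(a = rnorm(15, 0, 1), b = rnorm(15, 0.2, 1), c = rnorm(15, 3, 1))
  crP <- gatedCompare(norm)
  if (crP@branch == "parametric") {
    expect_equal(crP@omnibus$method, "one-way ANOVA")
    expect_true(all(crP@pairwise$method == "Tukey"))
    crD <- gatedCompare(norm, posthoc = "dunnett", control = "a")
    expect_equal(nrow(crD@pairwise), 2)
    expect_true(all(crD@pairwise$method == "Dunnett"))
  }
})

test_that("mixed-measures parametric branch reports the group effect", {
  set.seed(47)
  df <- expand.grid(subject = paste0("s", 1:6), day = c("d1", "d2", "d3"))
  df$group <- rep(c("air", "veh"), each = 3)[match(df$subject,
    paste0("s", 1:6))]
  df$value <- rnorm(nrow(df)) + ifelse(df$group == "air", 0, 0.3)
  cr <- gatedCompare(df, pairedWithin = "day")
  expect_true(cr@branch %in% c("parametric", "nonparametric"))
  if (cr@branch == "parametric") {
    expect_match(cr@omnibus$method, "mixed")
    expect_true(is.finite(cr@omnibus$p.value))
  }
})

test_that("null gated pipeline keeps the BH-adjusted rejection rate low", {
  set.seed(48)
  rej <- 0; tot <- 0
  for (r in 1:200) {
    cr <- gatedCompare(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
    rej <- rej + sum(cr@pairwise$p.adj < 0.05)
    tot <- tot + nrow(cr@pairwise)
  }
  expect_lte(rej / tot, 0.08)
})

test_that("agreement is zero on identity and exact on a uniform offset", {
  hand <- matrix(c(50, 20, 30, 20, 40, 25, 35, 20), 2, 4,
    dimnames = list(c("s1", "s2"), paste0("Q", 1:4)))
  ag <- agreement(hand, hand)
  expect_equal(ag@meanAbsErrorPct, 0)
  expect_equal(ag@pairedT$p.value, 1)

  off <- agreement(hand, hand + 1.2, durationS = 120)
  expect_equal(off@cells$diffPct, rep(1, 8))
  expect_equal(off@meanAbsErrorPct, 1)
  expect_equal(off@pairedT$p.value, 1)

  bad <- hand
  rownames(bad) <- c("s1", "s9")
  expect_error(agreement(hand, bad), "s9")
})

test_that("confusion metrics reproduce the printed validation arithmetic", {
  got <- confusionMetrics(confusionRates(6.8, 2.0, 84.0, 7.2))
  expect_equal(unname(got["recall_pct"]), 97.7)
  expect_equal(unname(got["precision_pct"]), 92.5)
  perfect <- confusionMetrics(confusionRates(0, 0, 100, 0))
  expect_equal(unname(perfect[c("recall_pct", "precision_pct")]), c(100, 100))
  half <- confusionMetrics(confusionRates(50, 0, 50, 0))
  expect_equal(unname(half["precision_pct"]), 50)
  expect_error(confusionRates(50, 50, 50, 50), "sum")
  expect_error(confusionMetrics(confusionRates(0, 50, 0, 50)), "precision")
  expect_error(confusionMetrics(confusionRates(50, 0, 0, 50)), "recall")
})

test_that("daily trend OLS matches the normal equations", {
  exact <- dailyTrend(1:5, 2 * (1:5) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r.squared, 1)

  flat <- dailyTrend(1:6, rep(3, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r.squared, 0)

  set.seed(49)
  d <- sample(1:14, 5); v <- rnorm(5)
  got <- dailyTrend(d, v)
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  expect_equal(got$intercept, beta[1], tolerance = 1e-10)
  expect_equal(got$slope, beta[2], tolerance = 1e-10)
  expect_error(dailyTrend(rep(2, 4), rnorm(4)), "distinct")
})
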