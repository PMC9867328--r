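test_that("paired t-test matches the closed form and handles degeneracy", {
  # d = [1,2,3]: t = 2 / (1/sqrt(3)) = 3.464, df = 2
  b <- c(1, 2, 3); a <- b + c(1, 2, 3)
  tt <- pairedTTest(a, b)
  expect_equal(tt$t, sqrt(3) * 2, tolerance = 1e-6)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 2 * stats::pt(-sqrt(12), df = 2), tolerance = 1e-9)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  # symmetry
  ts <- pairedTTest(b, a)
  expect_equal(ts$t, -tt$t)
  expect_equal(ts$p, tt$p)
  # a = b: zero-variance all-zero differences
  z <- pairedTTest(b, b)
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  # constant non-zero differences flagged, reported as unbounded evidence
  d <- pairedTTest(b + 1, b)
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  expect_equal(d$t, Inf)
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("paired t-test p agrees with a permutation oracle", {
  set.seed(40)
  for (i in 1:10) {
    n <- sample(8:15, 1)
    a <- rnorm(n, mean = 0.3)
    b <- rnorm(n)
    tt <- pairedTTest(a, b)
    d <- a - b
    tobs <- abs(mean(d) / (sd(d) / sqrt(n)))
    perm <- replicate(4000, {
      s <- sample(c(-1, 1), n, replace = TRUE)
      abs(mean(s * d) / (sd(s * d) / sqrt(n)))
    })
    pperm <- mean(perm >= tobs - 1e-12)
    expect_lt(abs(tt$p - pperm), 4 * sqrt(pperm * (1 - pperm) / 4000) + 0.02)
  }
})

test_that("Holm adjustment matches the step-down rule", {
  expect_equal(holmBonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmBonferroni(0.2), 0.2)
  expect_equal(holmBonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holmBonferroni(c(0.1, 1.3)), "\\[0, 1\\]")
  # properties: adjusted >= raw, capped at 1, monotone in raw order
  set.seed(41)
  p <- runif(8)
  q <- holmBonferroni(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("Cliff's delta: worked example, bounds, antisymmetry", {
  expect_equal(cliffsDelta(c(1, 3), c(2, 4)), -0.5)
  expect_equal(cliffsDelta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffsDelta(1:5, 1:5), 0)
  expect_error(cliffsDelta(numeric(0), 1), "empty")
  set.seed(42)
  a <- rnorm(15); b <- rnorm(12)
  expect_equal(cliffsDelta(a, b), -cliffsDelta(b, a))
  # invariant under a joint strictly monotone transform
  expect_equal(cliffsDelta(exp(a), exp(b)), cliffsDelta(a, b))
})

test_that("feature-set comparison builds the full family with Holm", {
  subj <- sprintf("S%02d", 1:12)
  set.seed(43)
  base <- runif(12, 0.7, 0.9)
  res <- rbind(
    data.frame(subject = subj, featureSet = "fractal", classifier = "cart",
               mean = base + 0.10),
    data.frame(subject = subj, featureSet = "statistical",
               classifier = "cart", mean = base + rnorm(12, 0, 0.01)),
    data.frame(subject = subj, featureSet = "hjorth", classifier = "cart",
               mean = base))
  cmp <- compareFeatureSets(res, reference = "fractal", classifier = "cart")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$p_holm >= cmp$p_raw))
  # uniform +10 point advantage: delta near 1, tiny p
  hj <- cmp[cmp$pair == "fractal vs hjorth", ]
  expect_lt(hj$p_raw, 0.001)
  expect_gt(hj$cliffs_delta, 0.5)
  # identical accuracies: delta 0, p_holm 1
  res2 <- rbind(res[res$featureSet != "hjorth", ],
                data.frame(subject = subj, featureSet = "hjorth",
                           classifier = "cart", mean = base + 0.10))
  cmp2 <- compareFeatureSets(res2, reference = "fractal")
  hj2 <- cmp2[cmp2$pair == "fractal vs hjorth", ]
  expect_equal(hj2$cliffs_delta, 0)
  expect_equal(hj2$p_holm, 1)
  # missing subject in one set is an error naming it
  expect_error(compareFeatureSets(res[-1, ], reference = "fractal"), "S01")
})

test_that("topography export z-scores channels and recovers planted effects", {
  # plant a frontal-only class effect on AF3/AF4
  set.seed(44)
  n <- 120
  chans <- epocChannels()
  arr <- array(rnorm(n * 14 * 256), c(n, 14, 256),
               dimnames = list(NULL, chans, NULL))
  labs <- rep(0:1, each = n / 2)
  for (e in which(labs == 1))
    arr[e, c("AF3", "AF4"), ] <- arr[e, c("AF3", "AF4"), ] * 3
  ep <- EEGEpochs(arr, labels = labs, dimension = "valence")
  ft <- assembleFeatureTable(ep, sets = "statistical")
  topo <- topographyExport(ft, "stat_std")
  expect_equal(nrow(topo), 28)
  wide <- merge(topo[topo$class == "high", c("channel", "z")],
                topo[topo$class == "low", c("channel", "z")],
                by = "channel", suffixes = c("_hi", "_lo"))
  gap <- abs(wide$z_hi - wide$z_lo)
  top2 <- wide$channel[order(gap, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("AF3", "AF4"))
  # a feature identical across classes yields identical maps: duplicate the
  # same epochs under both labels
  arr0 <- array(rnorm(20 * 14 * 256), c(20, 14, 256),
                dimnames = list(NULL, chans, NULL))
  arr0 <- arr0[rep(1:20, 2), , ]
  dimnames(arr0)[[2]] <- chans
  ep0 <- EEGEpochs(arr0, labels = rep(0:1, each = 20),
                   dimension = "valence")
  ft0 <- assembleFeatureTable(ep0, sets = "hjorth")
  topo0 <- topographyExport(ft0, "hjorth_mobility")
  expect_equal(topo0$z[topo0$class == "high"],
               topo0$z[topo0$class == "low"], tolerance = 1e-12)
  expect_error(topographyExport(ft0, "nonexistent"), "missing")
})
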