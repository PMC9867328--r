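test_that("fBm generator: parameter validation, determinism, Brownian case", {
  expect_error(genFBM(0, 100, seed = 1), "hurst")
  expect_error(genFBM(1.2, 100, seed = 1), "hurst")
  expect_identical(genFBM(0.6, 512, seed = 42), genFBM(0.6, 512, seed = 42))
  # H = 0.5 is ordinary Brownian motion: increments are white
  inc <- diff(genFBM(0.5, 1024, seed = 7))
  r <- stats::cor(inc[-1], inc[-length(inc)])
  expect_lt(abs(r), 0.1)
})

test_that("fBm increments follow the fGn autocovariance", {
  # lag-1 autocorrelation of fGn is 2^(2H-1) - 1
  for (H in c(0.3, 0.7)) {
    r <- mean(sapply(1:10, function(s) {
      inc <- diff(genFBM(H, 4096, seed = s))
      stats::cor(inc[-1], inc[-length(inc)])
    }))
    expect_lt(abs(r - (2^(2 * H - 1) - 1)), 0.05)
  }
})

test_that("Higuchi FD recovers 2 - H on fBm paths", {
  for (H in c(0.3, 0.5, 0.7)) {
    fds <- sapply(1:20, function(s) higuchiFD(genFBM(H, 2048, seed = s)))
    expect_lt(abs(mean(fds) - (2 - H)), 0.15)
  }
})

test_that("mean Higuchi FD decreases as Hurst increases", {
  means <- sapply(c(0.3, 0.5, 0.7), function(H)
    mean(sapply(1:20, function(s) higuchiFD(genFBM(H, 2048, seed = s)))))
  expect_true(all(diff(means) < 0))
})

test_that("Weierstrass series has the closed-form dimension", {
  w <- genWeierstrass(0.5, 4, nTerms = 30, n = 4096)
  expect_equal(attr(w, "dimension"), 1.5)
  expect_lt(abs(higuchiFD(w) - 1.5), 0.1)
  # single term is a pure cosine: smooth-curve limit
  expect_lte(higuchiFD(genWeierstrass(0.5, 4, nTerms = 1, n = 1024)), 1.05)
  expect_error(genWeierstrass(0.2, 4), "a \\* b")
})

test_that("QPC generator validates frequencies and plants coupling", {
  expect_error(genQPC(40, 40, fs = 128, n = 256), "aliasing")
  # averaged complex bispectrum peaks at the coupling bin iff coupled
  avg <- function(coupled, seeds) {
    acc <- 0
    for (s in seeds) {
      g <- bispectrum(genQPC(10, 21, 128, 256, coupled = coupled, seed = s))
      acc <- acc + g$bis
    }
    acc / length(seeds)
  }
  Bc <- avg(TRUE, 1:30)
  Bu <- avg(FALSE, 101:130)
  # bin indices: 0.5 Hz resolution, f1 = 21 -> bin 43 (1-based), f2 = 10 -> 21
  peak <- which.max(Mod(Bc))
  expect_equal(c((peak - 1) %% 129, (peak - 1) %/% 129), c(42, 20))
  expect_lt(Mod(Bu[43, 21]), 0.2 * Mod(Bc[43, 21]))
})

test_that("synthetic dataset is reproducible and label-faithful", {
  cfg <- synthConfig(nSubjects = 1, nTrialsPerSubject = 4,
                     trialDuration = 5, ratingNoiseSd = 0, seed = 11)
  ds1 <- genDataset(cfg)
  ds2 <- genDataset(cfg)
  expect_identical(lapply(ds1$recordings, eegData),
                   lapply(ds2$recordings, eegData))
  expect_identical(ds1$ratings, ds2$ratings)
  # noiseless ratings: midpoint binarization recovers the planted class
  tr <- merge(ds1$ratings, ds1$truth)
  expect_equal(binarizeRatings(tr$valence, 1, 9), tr$class)
  expect_equal(binarizeRatings(tr$arousal, 1, 9), tr$class)
})

test_that("artifact injection is rejected by the amplitude rule", {
  cfg <- synthConfig(nSubjects = 1, nTrialsPerSubject = 4,
                     trialDuration = 60, artifactRate = 2, seed = 5)
  ds <- genDataset(cfg)
  ep <- buildEpochSet(ds$recordings, ds$ratings, "valence")
  # ~2 artifacts/minute over 4 one-minute trials: several epochs rejected,
  # and every kept epoch respects the bound
  expect_gt(nRejected(ep), 0)
  expect_lte(max(abs(eegData(ep))), 100)
})

test_that("class fractality separates epochs of the two classes", {
  cfg <- synthConfig(nSubjects = 2, nTrialsPerSubject = 8,
                     trialDuration = 30, ratingNoiseSd = 0,
                     artifactRate = 0, seed = 21)
  ds <- genDataset(cfg)
  ep <- buildEpochSet(ds$recordings, ds$ratings, "valence")
  expect_gte(dim(eegData(ep))[1], 200)
  hfd <- apply(eegData(ep), 1, function(m) mean(apply(m, 1, higuchiFD)))
  lab <- epochLabels(ep)
  # class 0 has the lower Hurst exponent, hence the rougher signal
  tt <- t.test(hfd[lab == 0], hfd[lab == 1], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("epochs bundle round-trips through disk", {
  ep <- fractalEpochs(nPerClass = 3)
  dir <- tempfile("bundle")
  writeEpochsBundle(ep, dir)
  back <- readEpochsBundle(dir)
  expect_equal(eegData(back), eegData(ep), tolerance = 1e-12)
  expect_identical(epochLabels(back), epochLabels(ep))
  expect_identical(channelNames(back), channelNames(ep))
  expect_identical(subjectIds(back), subjectIds(ep))
  unlink(dir, recursive = TRUE)
})

test_that("ratings CSV round-trips", {
  ds <- genDataset(synthConfig(nSubjects = 1, nTrialsPerSubject = 3,
                               trialDuration = 2, seed = 2))
  f <- tempfile(fileext = ".csv")
  writeRatings(ds$ratings, f)
  back <- readRatings(f)
  expect_equal(back$valence, ds$ratings$valence, tolerance = 1e-9)
  expect_identical(back$subject, ds$ratings$subject)
  unlink(f)
})
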