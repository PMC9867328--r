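test_that("feature table has the published arity per channel", {
  ep <- fractalEpochs(nPerClass = 3, nChannels = 2)
  ft <- assembleFeatureTable(ep)
  rd <- SummarizedExperiment::rowData(ft)
  arities <- table(rd$set[rd$channel == "CH1"])
  expect_equal(as.integer(arities[c("statistical", "wavelet", "fractal",
                                    "hjorth", "hos")]),
               c(9L, 24L, 3L, 2L, 4L))
  expect_equal(nrow(ft), 42 * 2)
  ftf <- assembleFeatureTable(ep, sets = "fractal")
  expect_equal(nrow(ftf), 3 * 2)
  expect_error(assembleFeatureTable(ep, sets = "entropy"), "unknown")
  # column ordering: set-by-set, then channel-by-channel
  expect_identical(rownames(ft)[1:9], paste0(names(
    statisticalFeatures(sin(1:256))), "_CH1"))
  expect_identical(rd$set[1:18], rep("statistical", 18))
})

test_that("empty epoch sets yield an empty table without error", {
  ep <- EEGEpochs(array(0, c(0, 2, 256),
                        dimnames = list(NULL, c("A", "B"), NULL)),
                  labels = integer(0), subjectId = character(0),
                  trialId = character(0))
  ft <- assembleFeatureTable(ep, sets = "fractal")
  expect_equal(dim(ft), c(6L, 0L))
})

test_that("standardization uses train statistics only", {
  set.seed(20)
  tr <- cbind(a = rnorm(50, 5, 2), b = rep(7, 50))
  te <- cbind(a = rnorm(20, 5, 2), b = rep(7, 20))
  s <- standardizeFeatures(tr, te)
  expect_equal(mean(s$train[, "a"]), 0, tolerance = 1e-12)
  expect_equal(sd(s$train[, "a"]), 1, tolerance = 1e-9)
  # zero-SD column: centred, not scaled
  expect_true(all(s$train[, "b"] == 0))
  expect_true(all(s$test[, "b"] == 0))
  # test transformed with train statistics
  expect_equal(s$test[, "a"], (te[, "a"] - mean(tr[, "a"])) / sd(tr[, "a"]),
               tolerance = 1e-12)
  s2 <- standardizeFeatures(tr, tr)
  expect_equal(unname(s2$train), unname(s2$test), tolerance = 1e-12)
})

test_that("GSVM separates blobs, is chance on null data, deterministic", {
  set.seed(21)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(2 * n), n) + 5 * cbind(y, y)
  m <- fitGSVM(x, y, cost = 10, gamma = 0.5)
  expect_equal(mean(predict(m, x) == y), 1.0)
  # null data: held-out accuracy inside the binomial chance band
  nl <- nullFeatureMatrix(n = 500, p = 5, seed = 22)
  half <- 1:250
  m0 <- fitGSVM(nl$x[half, ], nl$y[half])
  acc <- mean(predict(m0, nl$x[-half, ]) == nl$y[-half])
  expect_gte(acc, 0.40); expect_lte(acc, 0.60)
  m2 <- fitGSVM(x, y, cost = 10, gamma = 0.5)
  expect_identical(predict(m, x), predict(m2, x))
  expect_error(fitGSVM(x, rep(1, n)), "single class")
})

test_that("CART ensemble separates blobs and handles 9:1 imbalance", {
  set.seed(23)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(2 * n), n) + 5 * cbind(y, y)
  colnames(x) <- c("u", "v")
  m <- fitCARTEnsemble(x, y, nCycles = 20, seed = 1)
  expect_gte(mean(predict(m, x) == y), 0.99)
  # imbalanced null: RUS-boosting keeps minority predictions alive
  set.seed(24)
  ni <- 400
  yi <- rep(c(0, 1), c(360, 40))
  xi <- matrix(rnorm(2 * ni), ni, dimnames = list(NULL, c("u", "v")))
  mi <- fitCARTEnsemble(xi, yi, nCycles = 30, minLeaf = 5, seed = 2)
  set.seed(25)
  xh <- matrix(rnorm(2 * 300), 300, dimnames = list(NULL, c("u", "v")))
  expect_gte(mean(predict(mi, xh) == 1), 0.10)
  # boundary configuration: a single undersampled tree
  m1 <- fitCARTEnsemble(x, y, nCycles = 1, learnRate = 1, seed = 3)
  expect_length(m1$trees, 1)
  expect_gte(mean(predict(m1, x) == y), 0.99)
})

test_that("native CART engine agrees with the rpart engine on fitted folds", {
  set.seed(26)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(3 * n), n, dimnames = list(NULL, c("a", "b", "c")))
  x[, 1] <- x[, 1] + 2.5 * y
  mn <- fitCARTEnsemble(x, y, nCycles = 10, seed = 7, engine = "native")
  mr <- fitCARTEnsemble(x, y, nCycles = 10, seed = 7, engine = "rpart")
  # same learning problem, same protocol: near-identical training behaviour
  expect_gt(mean(predict(mn, x) == predict(mr, x)), 0.9)
  expect_gte(mean(predict(mn, x) == y), 0.9)
  expect_gte(mean(predict(mr, x) == y), 0.9)
})

test_that("nested CV recovers planted fractality and is deterministic", {
  ep <- fractalEpochs(nPerClass = 40, nChannels = 2, seed = 31)
  ft <- assembleFeatureTable(ep, sets = "fractal")
  cfg <- cvConfig(classifier = "cart", searchBudget = 4, seed = 5)
  res <- nestedCV(ft, cfg)
  expect_length(res$foldAccuracies, 4)
  expect_equal(res$meanAccuracy, mean(res$foldAccuracies))
  expect_gte(res$meanAccuracy, 0.8)
  res2 <- nestedCV(ft, cfg)
  expect_identical(res$foldAccuracies, res2$foldAccuracies)
})

test_that("outer folds are disjoint, covering, and class-stratified", {
  y <- rep(0:1, c(41, 43))
  set.seed(9)
  fold <- fractalEEG:::stratifiedFolds(y, 4)
  expect_setequal(unique(fold), 1:4)
  expect_equal(length(fold), 84)
  for (f in 1:4) {
    n1 <- sum(y[fold == f] == 1)
    expect_lte(abs(n1 - 43 / 4), 1)
    n0 <- sum(y[fold == f] == 0)
    expect_lte(abs(n0 - 41 / 4), 1)
  }
  # trial-grouped splitting keeps whole trials in one fold
  groups <- rep(sprintf("T%02d", 1:21), each = 4)
  foldg <- fractalEEG:::stratifiedFolds(rep(0:1, 42), 4, groups = groups)
  expect_true(all(tapply(foldg, groups, function(v) length(unique(v))) == 1))
})

test_that("label-shuffled data scores at chance", {
  nl <- nullFeatureMatrix(n = 400, p = 10, seed = 33)
  res <- nestedCV(nl$x, cvConfig(classifier = "cart", searchBudget = 2,
                                 seed = 3), y = nl$y)
  expect_gte(res$meanAccuracy, 0.40)
  expect_lte(res$meanAccuracy, 0.60)
})

test_that("the subject driver returns the long results format", {
  ep <- fractalEpochs(nPerClass = 20, nChannels = 2, seed = 35)
  ft <- assembleFeatureTable(ep, sets = c("fractal", "hjorth"))
  res <- subjectCV(ft, sets = c("fractal", "hjorth", "combined"),
                   classifiers = "cart",
                   config = cvConfig(classifier = "cart", searchBudget = 2,
                                     seed = 2))
  expect_equal(nrow(res), 3)
  expect_named(res, c("subject", "featureSet", "classifier",
                      paste0("fold", 1:4), "mean"))
  expect_equal(res$mean, rowMeans(res[, paste0("fold", 1:4)]))
})
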