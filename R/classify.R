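featureSetNames <- c("statistical", "wavelet", "fractal", "hjorth", "hos")

# per-channel feature block for one epoch; order within each set is fixed
channelFeatures <- function(x, sets, kmax = 10) {
  out <- c()
  for (s in sets) {
    out <- c(out, switch(s,
      statistical = statisticalFeatures(x),
      wavelet = waveletFeatures(cwtMorlet(x)),
      fractal = c(fd_katz = katzFD(x), fd_petrosian = petrosianFD(x),
                  fd_higuchi = higuchiFD(x, kmax = kmax)),
      hjorth = hjorthParameters(x),
      hos = hosFeatures(bispectrum(x)),
      stop("unknown feature set: ", s)))
  }
  out
}

featureSetArity <- c(statistical = 9L, wavelet = 24L, fractal = 3L,
                     hjorth = 2L, hos = 4L)

#' Assemble the per-epoch feature table
#'
#' Runs the requested feature extractors on every channel of every epoch and
#' returns an [EEGFeatures-class] object (features x epochs). Columns are
#' epochs; rows are ordered set-by-set, then channel-by-channel within each
#' set, then feature-by-feature, and named `<feature>_<channel>`. Non-finite
#' values from degenerate epochs are zero-filled.
#'
#' @param epochs an [EEGEpochs-class] object with 0/1 labels.
#' @param sets feature sets to extract, a subset of
#'   `c("statistical", "wavelet", "fractal", "hjorth", "hos")`.
#' @param kmax Higuchi maximum lag.
#' @return An [EEGFeatures-class] object.
#' @examples
#' ep <- EEGEpochs(array(rnorm(4 * 2 * 256), c(4, 2, 256),
#'                       dimnames = list(NULL, c("O1", "O2"), NULL)),
#'                 labels = c(0, 1, 0, 1), dimension = "valence")
#' ft <- assembleFeatureTable(ep, sets = "fractal")
#' dim(ft)  # 6 features x 4 epochs
#' @export
assembleFeatureTable <- function(epochs, sets = featureSetNames, kmax = 10) {
  stopifnot(is(epochs, "EEGEpochs"))
  bad <- setdiff(sets, featureSetNames)
  if (length(bad)) stop("unknown feature set: ", paste(bad, collapse = ", "))
  chans <- channelNames(epochs)
  nE <- dim(epochs@data)[1]

  rowSet <- c(); rowChan <- c(); rowFeat <- c()
  for (s in sets) for (ch in chans) {
    nm <- names(channelFeatures(sin(seq_len(dim(epochs@data)[3])), s, kmax))
    rowSet <- c(rowSet, rep(s, length(nm)))
    rowChan <- c(rowChan, rep(ch, length(nm)))
    rowFeat <- c(rowFeat, nm)
  }
  mat <- matrix(0, length(rowFeat), nE,
                dimnames = list(paste0(rowFeat, "_", rowChan), NULL))
  if (nE > 0) {
    for (e in seq_len(nE)) {
      col <- c()
      for (s in sets) for (ci in seq_along(chans))
        col <- c(col, channelFeatures(epochs@data[e, ci, ], s, kmax))
      mat[, e] <- col
    }
  }
  mat[!is.finite(mat)] <- 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(set = rowSet, channel = rowChan,
                                   feature = rowFeat),
    colData = S4Vectors::DataFrame(
      label = epochs@labels,
      dimension = rep_len(epochs@dimension, nE),
      subjectId = epochs@subjectId, trialId = epochs@trialId))
  new("EEGFeatures", se)
}

#' Train-fold standardization
#'
#' Z-scores predictor columns using the training fold's mean and SD only;
#' the test fold is transformed with the training statistics (no leakage).
#' Zero-SD training columns are centred but not scaled.
#'
#' @param train,test numeric matrices, observations x features.
#' @return List with `train`, `test` (NULL if not supplied), `center`,
#'   `scale`.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  stopifnot(nrow(train) >= 1)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  z <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = z(train), test = if (!is.null(test)) z(test),
       center = ctr, scale = scl)
}

#' RBF-kernel support vector machine
#'
#' Thin wrapper over [e1071::svm()] with a Gaussian radial basis kernel and
#' no internal rescaling (predictors are standardized by the caller). The two
#' tuned hyperparameters are the box constraint `cost` and the kernel width
#' `gamma`.
#'
#' @param x predictors, observations x features (standardized).
#' @param y 0/1 labels with both classes present.
#' @param cost box constraint C.
#' @param gamma RBF kernel coefficient.
#' @return Fitted model of class `"gsvmModel"`; use [stats::predict()] to get
#'   0/1 labels.
#' @export
fitGSVM <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  if (length(unique(y)) < 2) stop("training fold has a single class")
  m <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                  cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = m), class = "gsvmModel")
}

#' @export
predict.gsvmModel <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$fit, newdata)))
}

#' Random-undersampling boosted CART ensemble
#'
#' AdaBoost-style ensemble of CART trees in which every boosting round trains
#' on a class-balanced random undersample drawn with probability proportional
#' to the current boosting weights (RUS-boosting), the standard remedy for
#' class imbalance. `learnRate` shrinks each round's vote weight; with
#' `nCycles = 1` and `learnRate = 1` the model reduces to a single
#' undersampled tree. `minLeaf` is enforced per tree via `rpart`'s
#' `minbucket`.
#'
#' @param x predictors, observations x features.
#' @param y 0/1 labels with both classes present.
#' @param nCycles number of boosting rounds.
#' @param learnRate shrinkage of the per-round vote weight, in (0, 1].
#' @param minLeaf minimum observations in any terminal tree node.
#' @param seed optional integer seed for the undersampling draws.
#' @param engine `"native"` (the package's compiled Gini CART, fast enough
#'   for thousands of boosting fits) or `"rpart"` ([rpart::rpart()] with the
#'   equivalent control settings, kept as a cross-check).
#' @return Fitted model of class `"cartEnsemble"`; use [stats::predict()].
#' @export
fitCARTEnsemble <- function(x, y, nCycles = 100, learnRate = 0.5,
                            minLeaf = 5, seed = NULL,
                            engine = c("native", "rpart")) {
  engine <- match.arg(engine)
  if (length(unique(y)) < 2) stop("training fold has a single class")
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (engine == "native") {
    fit <- .rusBoost(x, y, as.integer(nCycles), learnRate,
                     as.integer(minLeaf), max(2L * as.integer(minLeaf), 4L),
                     0.01, 30L)
    return(structure(list(trees = fit$trees, alphas = fit$alphas,
                          engine = engine, vars = colnames(x)),
                     class = "cartEnsemble"))
  }
  n <- length(y)
  w <- rep(1 / n, n)
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  nTake <- min(length(i0), length(i1))
  ctrl <- rpart::rpart.control(minbucket = minLeaf, cp = 0.01, xval = 0)
  fitTree <- function(take) {
    rpart::rpart(cls ~ ., method = "class", control = ctrl,
                 data = cbind(cls = factor(y[take], levels = c(0, 1)),
                              as.data.frame(x[take, , drop = FALSE])))
  }
  trees <- list(); alphas <- numeric()
  for (m in seq_len(nCycles)) {
    take <- c(sampleWeighted(i0, nTake, w), sampleWeighted(i1, nTake, w))
    fit <- fitTree(take)
    pred <- as.integer(predict(fit, as.data.frame(x), type = "class") == "1")
    err <- sum(w[pred != y])
    if (err >= 0.5) next            # weak learner no better than chance
    err <- max(err, 1e-10)
    a <- learnRate * 0.5 * log((1 - err) / err)
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, a)
  }
  if (!length(trees)) {             # fall back to one undersampled tree
    take <- c(sampleWeighted(i0, nTake, w), sampleWeighted(i1, nTake, w))
    trees <- list(fitTree(take))
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, engine = engine,
                 vars = colnames(x)), class = "cartEnsemble")
}

sampleWeighted <- function(idx, size, w) {
  if (length(idx) == 1L) return(rep(idx, length.out = size))
  if (size >= length(idx)) return(idx)
  sample(idx, size, prob = w[idx])
}

#' @export
predict.cartEnsemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$engine == "native")
    return(.ensemblePredict(object$trees, object$alphas, newdata))
  score <- rep(0, nrow(newdata))
  for (k in seq_along(object$trees)) {
    p <- as.integer(predict(object$trees[[k]], as.data.frame(newdata),
                            type = "class") == "1")
    score <- score + object$alphas[k] * (2 * p - 1)
  }
  as.integer(score > 0)
}

#' Nested cross-validation configuration
#'
#' @param outerFolds,innerFolds fold counts of the outer evaluation split and
#'   the inner hyperparameter-selection split.
#' @param classifier `"gsvm"` (RBF-SVM) or `"cart"` (RUS-boosted ensemble).
#' @param searchBudget number of random hyperparameter draws evaluated per
#'   outer fold.
#' @param seed integer seed driving fold assignment, the hyperparameter
#'   draws, and the ensemble's undersampling.
#' @param splitUnit `"epoch"` (stratified over epochs, the default) or
#'   `"trial"` (folds group whole trials, preventing trial identity leaking
#'   across folds).
#' @return A validated list of class `"CVConfig"`.
#' @export
cvConfig <- function(outerFolds = 4, innerFolds = 3,
                     classifier = c("gsvm", "cart"),
                     searchBudget = 20, seed = 1L,
                     splitUnit = c("epoch", "trial")) {
  classifier <- match.arg(classifier)
  splitUnit <- match.arg(splitUnit)
  stopifnot(outerFolds >= 2, innerFolds >= 2, searchBudget >= 1)
  structure(list(outerFolds = outerFolds, innerFolds = innerFolds,
                 classifier = classifier, searchBudget = searchBudget,
                 seed = as.integer(seed), splitUnit = splitUnit),
            class = "CVConfig")
}

# stratified fold assignment: within each class, shuffled round-robin
stratifiedFolds <- function(y, k, groups = NULL) {
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    for (cls in unique(y)) {
      gs <- sample(unique(groups[y == cls]))
      gf <- rep_len(seq_len(k), length(gs))
      for (gi in seq_along(gs)) fold[groups == gs[gi]] <- gf[gi]
    }
  }
  fold
}

sampleHyperparams <- function(classifier, budget) {
  lr <- function(lo, hi) exp(runif(budget, log(lo), log(hi)))
  if (classifier == "gsvm") {
    data.frame(cost = lr(1e-2, 1e3), gamma = lr(1e-3, 1e1))
  } else {
    data.frame(nCycles = round(lr(10, 300)), learnRate = lr(0.01, 1),
               minLeaf = sample(1:50, budget, replace = TRUE))
  }
}

fitOne <- function(classifier, x, y, hp) {
  if (classifier == "gsvm")
    fitGSVM(x, y, cost = hp$cost, gamma = hp$gamma)
  else
    fitCARTEnsemble(x, y, nCycles = hp$nCycles, learnRate = hp$learnRate,
                    minLeaf = hp$minLeaf)
}

#' Subject-dependent nested cross-validation
#'
#' Evaluates one feature table (one subject, one feature set) with the
#' paper-style protocol: a stratified outer 4-fold split; within each outer
#' training set, a seeded random search over the classifier's hyperparameter
#' space scored by stratified inner 3-fold accuracy (standardization is
#' refit on every inner training fold -- no leakage); the best configuration
#' is refit on the full outer training set and scored on the held-out outer
#' fold. Hyperparameter ranges: SVM box constraint in [1e-2, 1e3] and kernel
#' gamma in [1e-3, 1e1] (log-uniform); CART ensemble cycles in [10, 300]
#' (log-uniform), learning rate in [0.01, 1] (log-uniform), minimum leaf size
#' in [1, 50].
#'
#' @param x an [EEGFeatures-class] object, or a plain epochs x features
#'   matrix.
#' @param config a [cvConfig()] object.
#' @param y 0/1 labels (ignored when `x` is an [EEGFeatures-class]).
#' @param groups trial identifiers for `splitUnit = "trial"`.
#' @return A list with `foldAccuracies` (one per outer fold),
#'   `meanAccuracy`, `bestParams` (per-fold selected hyperparameters), and
#'   the `config`.
#' @export
nestedCV <- function(x, config = cvConfig(), y = NULL, groups = NULL) {
  if (is(x, "EEGFeatures")) {
    y <- epochLabels(x)
    groups <- trialIds(x)
    x <- t(SummarizedExperiment::assay(x, "features"))
  }
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (min(table(y)) < 2 * config$outerFolds)
    stop("too few epochs per class for ", config$outerFolds, "-fold CV")
  set.seed(config$seed)
  fold <- stratifiedFolds(y, config$outerFolds,
                          if (config$splitUnit == "trial") groups)
  accs <- numeric(config$outerFolds)
  best <- vector("list", config$outerFolds)
  for (f in seq_len(config$outerFolds)) {
    trIdx <- which(fold != f); teIdx <- which(fold == f)
    hp <- sampleHyperparams(config$classifier, config$searchBudget)
    inner <- stratifiedFolds(y[trIdx], config$innerFolds)
    scores <- numeric(nrow(hp))
    for (h in seq_len(nrow(hp))) {
      acc <- numeric(config$innerFolds)
      for (g in seq_len(config$innerFolds)) {
        itr <- trIdx[inner != g]; ite <- trIdx[inner == g]
        std <- standardizeFeatures(x[itr, , drop = FALSE],
                                   x[ite, , drop = FALSE])
        m <- fitOne(config$classifier, std$train, y[itr], hp[h, ])
        acc[g] <- mean(predict(m, std$test) == y[ite])
      }
      scores[h] <- mean(acc)
    }
    hbest <- which.max(scores)
    best[[f]] <- hp[hbest, ]
    std <- standardizeFeatures(x[trIdx, , drop = FALSE],
                               x[teIdx, , drop = FALSE])
    m <- fitOne(config$classifier, std$train, y[trIdx], hp[hbest, ])
    accs[f] <- mean(predict(m, std$test) == y[teIdx])
  }
  list(foldAccuracies = accs, meanAccuracy = mean(accs),
       bestParams = best, config = config)
}

#' Per-subject, per-set, per-classifier cross-validation driver
#'
#' Splits an [EEGFeatures-class] table by subject, subsets the rows of each
#' requested feature set (plus optionally the combined set), runs
#' [nestedCV()] for every classifier, and gathers the results in the long
#' format used by the feature-set comparison statistics. Subjects with too
#' few epochs per class are skipped with a message.
#'
#' @param features an [EEGFeatures-class] object covering all subjects.
#' @param sets feature sets to evaluate; `"combined"` uses all rows.
#' @param classifiers subset of `c("gsvm", "cart")`.
#' @param config a [cvConfig()]; its seed is offset per subject.
#' @return data.frame with columns subject, featureSet, classifier,
#'   fold1..foldK, mean.
#' @export
subjectCV <- function(features, sets = c(featureSetNames, "combined"),
                      classifiers = c("gsvm", "cart"),
                      config = cvConfig()) {
  stopifnot(is(features, "EEGFeatures"))
  rd <- SummarizedExperiment::rowData(features)
  out <- NULL
  subjects <- unique(subjectIds(features))
  for (si in seq_along(subjects)) {
    sub <- features[, subjectIds(features) == subjects[si]]
    if (min(table(factor(epochLabels(sub), levels = 0:1))) <
        2 * config$outerFolds) {
      message("skipping ", subjects[si], ": too few epochs per class")
      next
    }
    for (fs in sets) {
      rows <- if (fs == "combined") rep(TRUE, nrow(sub)) else rd$set == fs
      if (!any(rows)) stop("feature set not present in table: ", fs)
      for (cl in classifiers) {
        cfg <- config
        cfg$classifier <- cl
        cfg$seed <- config$seed + 1000L * si
        res <- nestedCV(sub[rows, ], cfg)
        row <- data.frame(subject = subjects[si], featureSet = fs,
                          classifier = cl, t(res$foldAccuracies),
                          mean = res$meanAccuracy)
        names(row)[4:(3 + length(res$foldAccuracies))] <-
          paste0("fold", seq_along(res$foldAccuracies))
        out <- rbind(out, row)
      }
    }
  }
  out
}
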