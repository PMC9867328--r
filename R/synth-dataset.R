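#' Synthetic emotion-EEG dataset configuration
#'
#' Bundles and validates the parameters of the synthetic dataset generator.
#' The two classes differ in per-channel fractality (Hurst exponent of the
#' fBm texture), alpha-band (10 Hz) amplitude, and quadratic phase coupling;
#' trial-level self-report ratings straddle the scale midpoint so that
#' midpoint binarization recovers the planted class up to rating noise.
#'
#' @param nSubjects,nTrialsPerSubject dataset size.
#' @param channelNames electrode montage (default the 14-channel EPOC set).
#' @param fsRaw raw sampling rate in Hz (>= 128).
#' @param trialDuration trial length in seconds.
#' @param hurstLowClass,hurstHighClass Hurst exponents of class 0 / class 1
#'   channel textures, both in (0, 1). Class 1 (high rating) gets the higher
#'   Hurst, i.e. the *smoother* signal.
#' @param alphaPowerRatio class-1 : class-0 alpha-band amplitude ratio.
#' @param qpcStrength amplitude multiplier of the coupled triplet planted in
#'   class-1 trials (class 0 receives an uncoupled triplet).
#' @param ratingScale `"1-9"` or `"1-5"`.
#' @param ratingNoiseSd SD of Gaussian noise added to ratings, rating units.
#' @param artifactRate blink-like artifacts per minute per trial.
#' @param amplitudeScale SD of each channel's fractal texture in
#'   microvolts; both classes share it, so class information lives in
#'   signal structure, not gross power.
#' @param seed integer master seed.
#' @return A validated list of class `"SynthConfig"`.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nTrialsPerSubject = 4)
#' @export
synthConfig <- function(nSubjects = 10, nTrialsPerSubject = 16,
                        channelNames = epocChannels(),
                        fsRaw = 256, trialDuration = 60,
                        hurstLowClass = 0.45, hurstHighClass = 0.7,
                        alphaPowerRatio = 1.5, qpcStrength = 1,
                        ratingScale = c("1-9", "1-5"),
                        ratingNoiseSd = 0.7, artifactRate = 2,
                        amplitudeScale = 10, seed = 1L) {
  ratingScale <- match.arg(ratingScale)
  stopifnot(nSubjects >= 1, nTrialsPerSubject >= 1,
            length(channelNames) >= 1, !anyDuplicated(channelNames),
            fsRaw >= 128, trialDuration > 0,
            abs(trialDuration * fsRaw - round(trialDuration * fsRaw)) < 1e-9,
            hurstLowClass > 0, hurstLowClass < 1,
            hurstHighClass > 0, hurstHighClass < 1,
            alphaPowerRatio >= 0, qpcStrength >= 0,
            ratingNoiseSd >= 0, artifactRate >= 0, amplitudeScale > 0)
  structure(list(
    nSubjects = nSubjects, nTrialsPerSubject = nTrialsPerSubject,
    channelNames = channelNames, fsRaw = fsRaw,
    trialDuration = trialDuration,
    hurstLowClass = hurstLowClass, hurstHighClass = hurstHighClass,
    alphaPowerRatio = alphaPowerRatio, qpcStrength = qpcStrength,
    ratingScale = ratingScale, ratingNoiseSd = ratingNoiseSd,
    artifactRate = artifactRate, amplitudeScale = amplitudeScale,
    seed = as.integer(seed)
  ), class = "SynthConfig")
}

ratingScaleRange <- function(scale) {
  switch(scale, "1-9" = c(1, 9), "1-5" = c(1, 5),
         stop("unknown rating scale: ", scale))
}

# One synthetic channel: fBm-derived fractal texture + alpha tone + QPC
# triplet. The texture is the fBm path band-limited above 1 Hz and scaled
# to unit SD, so the two classes differ in spectral-temporal structure
# (fractality) but not in gross in-band power -- an overall amplitude
# difference would hand every amplitude-sensitive feature a trivial class
# cue that is not among the intended planted effects. All stochastic draws
# come from the current RNG stream.
synthChannel <- function(n, fs, hurst, alphaAmp, qpcAmp, coupled) {
  fgn <- genFGN(hurst, n - 1)
  bw <- signal::butter(4, 1 / (fs / 2), type = "high")
  x <- zpFilter(bw, x = cumsum(c(0, fgn)))
  x <- x / sd(x)
  t <- (0:(n - 1)) / fs
  x <- x + alphaAmp * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  if (qpcAmp > 0) {
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
    x <- x + qpcAmp * (cos(2 * pi * 6 * t + p1) + cos(2 * pi * 9 * t + p2) +
                       cos(2 * pi * 15 * t + p3))
  }
  x
}

# 400 ms half-cosine blink deflections of 150-300 uV on the frontal channels
injectArtifacts <- function(data, fs, rate, durationS) {
  nArt <- rpois(1, rate * durationS / 60)
  if (nArt == 0) return(data)
  frontal <- grep("^AF", rownames(data))
  if (!length(frontal)) frontal <- 1L
  len <- round(0.4 * fs)
  bump <- sin(pi * (0:(len - 1)) / (len - 1))
  for (i in seq_len(nArt)) {
    start <- sample.int(ncol(data) - len, 1)
    amp <- runif(1, 150, 300) * sample(c(-1, 1), 1)
    idx <- start:(start + len - 1)
    data[frontal, idx] <- data[frontal, idx] +
      matrix(amp * bump, length(frontal), len, byrow = TRUE)
  }
  data
}

#' Generate a synthetic labeled emotion-EEG dataset
#'
#' Produces raw multichannel recordings, trial-level valence/arousal ratings,
#' and the planted ground-truth class per trial. Class 0 / class 1 are drawn
#' evenly within each subject. Each channel is an independent fBm-derived
#' fractal texture with the class Hurst exponent (band-limited above 1 Hz
#' and normalized to `amplitudeScale` microvolts SD for both classes), plus
#' a 10 Hz alpha tone whose amplitude carries the class ratio, plus a
#' three-cosine triplet that is quadratically phase-coupled only in class 1.
#' Ratings sit at the binarization threshold plus or minus 3/16 of the scale
#' range according to class, plus Gaussian noise.
#' Blink-like artifacts (>100 uV, 400 ms) are injected on frontal channels at
#' `artifactRate` per minute. Fully reproducible from `config$seed`.
#'
#' @param config a [synthConfig()] object.
#' @return A list with `recordings` (list of [EEGRecording-class]), `ratings`
#'   (data.frame: subject, trial, valence, arousal, scale_min, scale_max) and
#'   `truth` (data.frame: subject, trial, class).
#' @examples
#' ds <- genDataset(synthConfig(nSubjects = 1, nTrialsPerSubject = 2,
#'                              trialDuration = 10))
#' length(ds$recordings)
#' @export
genDataset <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  fs <- config$fsRaw
  n <- round(config$trialDuration * fs)
  sc <- ratingScaleRange(config$ratingScale)
  mid <- sc[2] / 2             # binarization threshold: 4.5 (1-9), 2.5 (1-5)
  effect <- 0.1875 * diff(sc)  # 1.5 rating units on the 1-9 scale
  alphaBase <- 0.05            # relative to the unit-SD fractal texture

  recordings <- list()
  ratings <- NULL
  truth <- NULL
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("S%02d", s)
    cls <- sample(rep(0:1, length.out = config$nTrialsPerSubject))
    for (tr in seq_len(config$nTrialsPerSubject)) {
      tid <- sprintf("T%02d", tr)
      k <- cls[tr]
      hurst <- if (k == 1) config$hurstHighClass else config$hurstLowClass
      alphaAmp <- alphaBase * if (k == 1) config$alphaPowerRatio else 1
      data <- t(vapply(config$channelNames, function(ch)
        synthChannel(n, fs, hurst, alphaAmp,
                     qpcAmp = 0.03 * config$qpcStrength, coupled = k == 1),
        numeric(n)))
      data <- config$amplitudeScale * data
      data <- injectArtifacts(data, fs, config$artifactRate,
                              config$trialDuration)
      rec <- EEGRecording(data, fs = fs, subjectId = sid, trialId = tid)
      recordings[[length(recordings) + 1L]] <- rec
      rate <- function() {
        r <- mid + (if (k == 1) effect else -effect) +
          config$ratingNoiseSd * rnorm(1)
        min(max(r, sc[1]), sc[2])
      }
      ratings <- rbind(ratings, data.frame(
        subject = sid, trial = tid, valence = rate(), arousal = rate(),
        scale_min = sc[1], scale_max = sc[2]))
      truth <- rbind(truth, data.frame(subject = sid, trial = tid, class = k))
    }
  }
  list(recordings = recordings, ratings = ratings, truth = truth)
}

#' Read and write trial-rating tables
#'
#' Plain-CSV persistence of trial-level self-report ratings with columns
#' `subject, trial, valence, arousal, scale_min, scale_max`.
#'
#' @param ratings data.frame as produced by [genDataset()].
#' @param path CSV file path.
#' @return `readRatings` returns the data.frame; `writeRatings` returns
#'   `path` invisibly.
#' @export
writeRatings <- function(ratings, path) {
  need <- c("subject", "trial", "valence", "arousal", "scale_min", "scale_max")
  stopifnot(all(need %in% names(ratings)))
  data.table::fwrite(ratings[need], path)
  invisible(path)
}

#' @rdname writeRatings
#' @export
readRatings <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Read and write the epochs bundle
#'
#' The epochs bundle is a plain-text on-disk form of an [EEGEpochs-class]
#' object: `data.csv` holds one row per (epoch, channel) with the 256 sample
#' values, and `meta.json` holds channel names, sampling rate, dimension,
#' labels, subject/trial identifiers and the rejection count.
#'
#' @param epochs an [EEGEpochs-class] object.
#' @param dir directory to create/read.
#' @return `readEpochsBundle` returns the [EEGEpochs-class] object;
#'   `writeEpochsBundle` returns `dir` invisibly.
#' @export
writeEpochsBundle <- function(epochs, dir) {
  stopifnot(is(epochs, "EEGEpochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  tab <- data.table::data.table(
    epoch = rep(seq_len(d[1]), each = d[2]),
    channel = rep(channelNames(epochs), d[1]))
  tab <- cbind(tab, data.table::as.data.table(flat))
  data.table::fwrite(tab, file.path(dir, "data.csv"))
  meta <- list(
    channels = channelNames(epochs), fs = epochs@fs,
    n_samples = d[3], n_epochs = d[1],
    dimension = epochs@dimension,
    labels = epochs@labels, subject = epochs@subjectId,
    trial = epochs@trialId, n_rejected = epochs@nRejected)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeEpochsBundle
#' @export
readEpochsBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tab <- data.table::fread(file.path(dir, "data.csv"))
  vals <- as.matrix(tab[, -(1:2)])
  nE <- meta$n_epochs; nC <- length(meta$channels); nS <- meta$n_samples
  arr <- aperm(array(t(vals), dim = c(nS, nC, nE)), c(3, 2, 1))
  dimnames(arr) <- list(NULL, meta$channels, NULL)
  labels <- meta$labels
  if (is.null(labels) || !length(labels)) labels <- rep(NA_integer_, nE)
  EEGEpochs(arr, labels = labels, dimension = meta$dimension,
            subjectId = meta$subject, trialId = meta$trial,
            nRejected = meta$n_rejected, fs = meta$fs)
}
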