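#' Signal-conditioning chain for raw EEG
#'
#' The standard chain applied to each raw recording, in fixed order:
#' mains notch -> 1 Hz high-pass -> down-sample to 128 Hz -> common average
#' reference -> 2 s epoching -> +/-100 uV artifact rejection. Each stage is
#' also exported on its own and appends its name to the recording's
#' processing log.
#'
#' @param rec an [EEGRecording-class] object.
#' @param q notch quality factor (centre frequency / -3 dB bandwidth).
#' @name preprocessing
NULL

# zero-phase filtering with odd-reflection padding: filtfilt alone leaves
# large transients at the signal edges for low-frequency filters
zpFilter <- function(filt, a = NULL, x) {
  n <- length(x)
  L <- min(n - 1L, 1024L)
  pre <- 2 * x[1] - x[(L + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - L)]
  xp <- c(pre, x, post)
  y <- if (is.null(a)) signal::filtfilt(filt, xp)
       else signal::filtfilt(filt = filt, a = a, xp)
  y[(L + 1):(L + n)]
}

applyChannels <- function(rec, f, stage) {
  out <- t(apply(rec@data, 1, f))
  rownames(out) <- rownames(rec@data)
  rec@data <- out
  rec@log <- c(rec@log, stage)
  rec
}

#' @describeIn preprocessing Zero-phase second-order IIR notch at the mains
#'   frequency (biquad design, default Q = 30).
#' @export
notchFilter <- function(rec, q = 30) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@mainsHz >= rec@fs / 2)
    stop("sampling rate too low for a ", rec@mainsHz, " Hz notch")
  w0 <- 2 * pi * rec@mainsHz / rec@fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  applyChannels(rec, function(x) zpFilter(b, a, x), "notch")
}

#' @describeIn preprocessing Zero-phase 4th-order Butterworth high-pass at
#'   1 Hz; removes DC offset and slow drift.
#' @export
highpassFilter <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs <= 2) stop("sampling rate too low for a 1 Hz high-pass")
  bw <- signal::butter(4, 1 / (rec@fs / 2), type = "high")
  applyChannels(rec, function(x) zpFilter(bw, x = x), "highpass")
}

#' @describeIn preprocessing Polyphase anti-aliased resampling to 128 Hz
#'   (identity when already at 128 Hz); upsampling is refused.
#' @export
resampleTo128 <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs < 128) stop("fs below 128 Hz; upsampling not supported")
  if (rec@fs == 128) {
    rec@log <- c(rec@log, "resample")
    return(rec)
  }
  nIn <- ncol(rec@data)
  nOut <- round(nIn * 128 / rec@fs)
  rec <- applyChannels(rec, function(x) fftResample(x, nOut), "resample")
  rec@fs <- 128
  rec
}

# band-limited (Fourier) resampling: truncate the spectrum at the new
# Nyquist frequency and invert at the new length; exact for band-limited
# periodic content, no group delay
fftResample <- function(x, nOut) {
  nIn <- length(x)
  X <- fft(x)
  Y <- complex(nOut)
  half <- floor(min(nIn, nOut) / 2)
  Y[1] <- X[1]
  Y[2:(half + 1)] <- X[2:(half + 1)]
  Y[nOut - (1:(half - 1)) + 1] <- X[nIn - (1:(half - 1)) + 1]
  Re(fft(Y, inverse = TRUE)) / nIn
}

#' @describeIn preprocessing Common average reference: subtracts the
#'   instantaneous cross-channel mean, so per-sample channel sums become 0.
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2) stop("CAR needs at least 2 channels")
  rec@data <- sweep(rec@data, 2, colMeans(rec@data))
  rec@log <- c(rec@log, "car")
  rec
}

#' @describeIn preprocessing Cuts the recording into non-overlapping 2 s
#'   epochs (256 samples at 128 Hz); the trailing partial epoch is dropped.
#'   Returns a list of channels x 256 matrices.
#' @export
segmentEpochs <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs != 128) stop("epoching expects data at 128 Hz")
  len <- 256L
  nEp <- floor(ncol(rec@data) / len)
  if (nEp == 0) return(list())
  lapply(seq_len(nEp), function(e)
    rec@data[, ((e - 1) * len + 1):(e * len), drop = FALSE])
}

#' Reject epochs exceeding +/-100 microvolts
#'
#' An epoch is removed iff any sample on any channel strictly exceeds 100 uV
#' in absolute value; an epoch peaking at exactly 100 uV is kept. Order of
#' the surviving epochs is preserved.
#'
#' @param epochs list of channels x samples matrices from [segmentEpochs()].
#' @param threshold amplitude bound in microvolts.
#' @return A list with `kept` (surviving epochs) and `nRejected`.
#' @export
rejectArtifacts <- function(epochs, threshold = 100) {
  bad <- vapply(epochs, function(e) max(abs(e)) > threshold, logical(1))
  list(kept = epochs[!bad], nRejected = sum(bad))
}

#' Binarize self-report ratings at the scale midpoint
#'
#' Labels a rating high (1) iff it is at or above the conventional midpoint
#' threshold, half the scale maximum: 4.5 on the 1-9 scale, 2.5 on the 1-5
#' scale. Ratings below the threshold are low (0). Already-binary labels on
#' a 0-1 "scale" pass through unchanged.
#'
#' @param rating numeric vector of ratings.
#' @param scaleMin,scaleMax rating scale limits.
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarizeRatings(c(2.4, 2.5), 1, 5)  # 0, 1
#' @export
binarizeRatings <- function(rating, scaleMin, scaleMax) {
  if (any(rating < scaleMin | rating > scaleMax))
    stop("rating outside the declared scale [", scaleMin, ", ", scaleMax, "]")
  if (scaleMin == 0 && scaleMax == 1 && all(rating %in% c(0, 1)))
    return(as.integer(rating))  # pre-binarized labels pass through
  as.integer(rating >= scaleMax / 2)
}

#' Run the full conditioning chain on one recording
#'
#' Applies notch -> high-pass -> resample -> CAR, then epochs and rejects
#' artifacts.
#'
#' @param rec an [EEGRecording-class] object.
#' @param q notch quality factor.
#' @return A list with `epochs` (list of channels x 256 matrices),
#'   `nRejected`, and `log` (the stage order actually applied).
#' @export
preprocessRecording <- function(rec, q = 30) {
  rec <- commonAverageReference(resampleTo128(highpassFilter(
    notchFilter(rec, q = q))))
  seg <- segmentEpochs(rec)
  rj <- rejectArtifacts(seg)
  list(epochs = rj$kept, nRejected = rj$nRejected,
       log = c(rec@log, "epoch", "reject"))
}

#' Build a labeled EpochSet from recordings and ratings
#'
#' Preprocesses every recording through the standard chain, labels each
#' surviving epoch by binarizing the trial's rating on the requested
#' dimension, and stacks everything into one [EEGEpochs-class] object.
#'
#' @param recordings list of [EEGRecording-class] objects.
#' @param ratings data.frame with columns subject, trial, valence, arousal,
#'   scale_min, scale_max.
#' @param dimension `"valence"` or `"arousal"`.
#' @param q notch quality factor.
#' @return An [EEGEpochs-class] object.
#' @export
buildEpochSet <- function(recordings, ratings, dimension = c("valence", "arousal"),
                          q = 30) {
  dimension <- match.arg(dimension)
  mats <- list(); labs <- integer(); subj <- character()
  tri <- character(); nRej <- 0L
  for (rec in recordings) {
    key <- ratings$subject == rec@subjectId & ratings$trial == rec@trialId
    if (!any(key))
      stop("no rating for ", rec@subjectId, "/", rec@trialId)
    row <- ratings[which(key)[1], ]
    lab <- binarizeRatings(row[[dimension]], row$scale_min, row$scale_max)
    pp <- preprocessRecording(rec, q = q)
    nRej <- nRej + pp$nRejected
    for (e in pp$epochs) {
      mats[[length(mats) + 1L]] <- e
      labs <- c(labs, lab)
      subj <- c(subj, rec@subjectId)
      tri <- c(tri, rec@trialId)
    }
  }
  if (!length(mats)) stop("no epochs survived preprocessing")
  nC <- nrow(mats[[1]]); nS <- ncol(mats[[1]])
  arr <- array(0, dim = c(length(mats), nC, nS),
               dimnames = list(NULL, rownames(mats[[1]]), NULL))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  EEGEpochs(arr, labels = labs, dimension = dimension,
            subjectId = subj, trialId = tri, nRejected = nRej, fs = 128)
}
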