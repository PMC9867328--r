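#' @import methods
#' @useDynLib fractalEEG, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats fft rnorm runif sd median coef lm t.test p.adjust
#'   quantile rpois predict approx setNames
NULL

#' Emotiv EPOC 14-channel 10-20 montage
#'
#' Channel names of the 14-electrode montage shared by consumer EEG headsets,
#' in the conventional left-frontal to right-frontal ordering. This is the
#' common-channel set used for topography export.
#'
#' @return Character vector of 14 channel names.
#' @examples
#' epocChannels()
#' @export
epocChannels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' EEGRecording: continuous multichannel EEG
#'
#' A continuous multichannel EEG recording in microvolts: a channels x samples
#' matrix plus sampling rate, channel names (rownames of the matrix), subject
#' and trial identifiers, the local mains frequency, and a log of the
#' preprocessing stages already applied.
#'
#' @slot data numeric matrix, channels x samples, in microvolts; rownames are
#'   the channel names.
#' @slot fs sampling rate in Hz.
#' @slot subjectId,trialId character scalars identifying the recording.
#' @slot mainsHz mains frequency, 50 or 60 Hz.
#' @slot log character vector of preprocessing stage names applied so far.
#'
#' @aliases EEGRecording-class
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    subjectId = "character",
    trialId = "character",
    mainsHz = "numeric",
    log = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains NA/NaN/Inf")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must have channel names as rownames")
  else if (anyDuplicated(rownames(object@data)))
    msg <- c(msg, "channel names must be unique")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (!object@mainsHz %in% c(50, 60))
    msg <- c(msg, "mainsHz must be 50 or 60")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix in microvolts.
#' @param fs sampling rate in Hz.
#' @param channelNames channel names; defaults to `rownames(data)`.
#' @param subjectId,trialId identifiers.
#' @param mainsHz mains frequency (50 or 60).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 256), 2,
#'                            dimnames = list(c("AF3", "AF4"), NULL)),
#'                     fs = 128)
#' samplingRate(rec)
#' @export
EEGRecording <- function(data, fs, channelNames = rownames(data),
                         subjectId = "S01", trialId = "T01", mainsHz = 50) {
  data <- as.matrix(data)
  if (!is.null(channelNames)) rownames(data) <- channelNames
  new("EEGRecording", data = data, fs = fs,
      subjectId = as.character(subjectId), trialId = as.character(trialId),
      mainsHz = mainsHz, log = character())
}

#' EEGEpochs: labeled fixed-length epochs
#'
#' Fixed-length 2 s epochs at 128 Hz (epochs x channels x 256 samples) with a
#' binary emotion label per epoch, the rating dimension the labels binarize,
#' per-epoch subject/trial identifiers, and the count of epochs rejected by
#' the amplitude criterion.
#'
#' @slot data numeric array, epochs x channels x samples (256), microvolts.
#' @slot labels integer vector, 0 = low, 1 = high (NA when unlabeled).
#' @slot dimension `"valence"` or `"arousal"`.
#' @slot subjectId,trialId character vectors, one entry per epoch.
#' @slot nRejected number of epochs removed by artifact rejection.
#' @slot fs sampling rate in Hz (128 after the standard chain).
#'
#' @aliases EEGEpochs-class
#' @export
setClass("EEGEpochs",
  representation(
    data = "array",
    labels = "integer",
    dimension = "character",
    subjectId = "character",
    trialId = "character",
    nRejected = "integer",
    fs = "numeric"
  )
)

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
  else {
    if (length(object@labels) != d[1])
      msg <- c(msg, "one label per epoch required")
    if (length(object@subjectId) != d[1] || length(object@trialId) != d[1])
      msg <- c(msg, "subjectId/trialId must have one entry per epoch")
    if (is.null(dimnames(object@data)[[2]]))
      msg <- c(msg, "channel names required on dim 2")
  }
  bad <- object@labels[!is.na(object@labels)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (!object@dimension %in% c("valence", "arousal", "none"))
    msg <- c(msg, "dimension must be 'valence', 'arousal' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpochs object
#'
#' @param data epochs x channels x samples array.
#' @param labels integer 0/1 per epoch (NA allowed).
#' @param dimension rating dimension the labels binarize.
#' @param subjectId,trialId per-epoch identifiers (recycled if scalar).
#' @param nRejected epochs removed by artifact rejection.
#' @param fs sampling rate in Hz.
#' @return An [EEGEpochs-class] object.
#' @export
EEGEpochs <- function(data, labels = rep(NA_integer_, dim(data)[1]),
                      dimension = "none",
                      subjectId = "S01", trialId = "T01",
                      nRejected = 0L, fs = 128) {
  n <- dim(data)[1]
  new("EEGEpochs", data = data, labels = as.integer(labels),
      dimension = dimension,
      subjectId = rep_len(as.character(subjectId), n),
      trialId = rep_len(as.character(trialId), n),
      nRejected = as.integer(nRejected), fs = fs)
}

#' EEGFeatures: per-epoch feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' features x epochs assay. `rowData` carries the feature set tag
#' (`set`: statistical, wavelet, fractal, hjorth or hos), the channel, and the
#' base feature name; `colData` carries the binary label, the rating
#' dimension, and per-epoch subject/trial identifiers.
#'
#' @aliases EEGFeatures-class
#' @export
setClass("EEGFeatures", contains = "SummarizedExperiment")

setValidity("EEGFeatures", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
    msg <- c(msg, "feature assay must be finite (degenerate features are zero-filled)")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("set", "channel", "feature") %in% colnames(rd)))
    msg <- c(msg, "rowData must have set/channel/feature")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "subjectId", "trialId") %in% colnames(cd)))
    msg <- c(msg, "colData must have label/subjectId/trialId")
  else if (!all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})
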