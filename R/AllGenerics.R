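#' Accessors for EEG containers
#'
#' `eegData` returns the numeric payload (matrix or array), `samplingRate` the
#' sampling frequency in Hz, `channelNames` the electrode labels,
#' `epochLabels` the binary labels, `nRejected` the artifact-rejection count,
#' and `processingLog` the ordered list of preprocessing stages applied.
#'
#' @param x an [EEGRecording-class], [EEGEpochs-class] or
#'   [EEGFeatures-class] object.
#' @return The corresponding slot value.
#' @name eeg-accessors
#' @aliases eegData samplingRate channelNames epochLabels nRejected
#'   processingLog subjectIds trialIds
#' @examples
#' rec <- EEGRecording(matrix(0, 2, 64, dimnames = list(c("O1", "O2"), NULL)),
#'                     fs = 128)
#' channelNames(rec)
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname eeg-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname eeg-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname eeg-accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname eeg-accessors
#' @export
setGeneric("nRejected", function(x) standardGeneric("nRejected"))
#' @rdname eeg-accessors
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
#' @rdname eeg-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname eeg-accessors
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname eeg-accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname eeg-accessors
setMethod("eegData", "EEGEpochs", function(x) x@data)
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGEpochs", function(x) x@fs)
#' @rdname eeg-accessors
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))
#' @rdname eeg-accessors
setMethod("channelNames", "EEGEpochs", function(x) dimnames(x@data)[[2]])
#' @rdname eeg-accessors
setMethod("epochLabels", "EEGEpochs", function(x) x@labels)
#' @rdname eeg-accessors
setMethod("epochLabels", "EEGFeatures",
          function(x) SummarizedExperiment::colData(x)$label)
#' @rdname eeg-accessors
setMethod("nRejected", "EEGEpochs", function(x) x@nRejected)
#' @rdname eeg-accessors
setMethod("processingLog", "EEGRecording", function(x) x@log)
#' @rdname eeg-accessors
setMethod("subjectIds", "EEGRecording", function(x) x@subjectId)
#' @rdname eeg-accessors
setMethod("subjectIds", "EEGEpochs", function(x) x@subjectId)
#' @rdname eeg-accessors
setMethod("subjectIds", "EEGFeatures",
          function(x) SummarizedExperiment::colData(x)$subjectId)
#' @rdname eeg-accessors
setMethod("trialIds", "EEGRecording", function(x) x@trialId)
#' @rdname eeg-accessors
setMethod("trialIds", "EEGEpochs", function(x) x@trialId)
#' @rdname eeg-accessors
setMethod("trialIds", "EEGFeatures",
          function(x) SummarizedExperiment::colData(x)$trialId)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", object@subjectId, "/", object@trialId, "\n")
  cat(" ", nrow(object@data), "channels x", ncol(object@data),
      "samples @", object@fs, "Hz  (mains", object@mainsHz, "Hz)\n")
  if (length(object@log))
    cat("  processed:", paste(object@log, collapse = " -> "), "\n")
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat("EEGEpochs:", d[1], "epochs x", d[2], "channels x", d[3],
      "samples @", object@fs, "Hz\n")
  cat("  dimension:", object@dimension,
      " labels:", sum(object@labels == 1L, na.rm = TRUE), "high /",
      sum(object@labels == 0L, na.rm = TRUE), "low\n")
  cat("  subjects:", length(unique(object@subjectId)),
      " rejected epochs:", object@nRejected, "\n")
})
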