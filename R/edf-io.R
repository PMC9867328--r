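## Minimal EDF (European Data Format) reader/writer for continuous
## multichannel recordings: 256-byte fixed header, 256 bytes per signal,
## 16-bit little-endian samples, linear digital->physical calibration.
## All signals must share one sampling rate; annotations are not supported.

edfField <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Read a continuous EDF recording
#'
#' Parses the standard EDF header and 16-bit sample records into an
#' [EEGRecording-class] object, applying the per-signal linear calibration to
#' physical units. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @param subjectId,trialId identifiers to attach.
#' @param mainsHz local mains frequency (50 or 60).
#' @return An [EEGRecording-class] object.
#' @export
readEDF <- function(path, subjectId = "S01", trialId = "T01", mainsHz = 50) {
  con <- file(path, "rb")
  on.exit(close(con))
  edfField(con, 8)                    # version
  edfField(con, 80); edfField(con, 80)  # patient, recording id
  edfField(con, 8); edfField(con, 8)    # start date, time
  edfField(con, 8)                    # header length
  edfField(con, 44)                   # reserved
  nRec <- as.integer(edfField(con, 8))
  recDur <- as.numeric(edfField(con, 8))
  ns <- as.integer(edfField(con, 4))
  get <- function(w) vapply(seq_len(ns), function(i) edfField(con, w), "")
  labels <- get(16)
  get(80)                              # transducer
  get(8)                               # physical dimension
  physMin <- as.numeric(get(8)); physMax <- as.numeric(get(8))
  digMin <- as.numeric(get(8)); digMax <- as.numeric(get(8))
  get(80)                              # prefilter
  spr <- as.integer(get(8))            # samples per record
  get(32)                              # reserved
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / recDur
  gain <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    m <- matrix(block, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(m) * gain + (physMin - digMin * gain)
  }
  rownames(data) <- labels
  EEGRecording(data, fs = fs, subjectId = subjectId, trialId = trialId,
               mainsHz = mainsHz)
}

#' Write a recording to EDF
#'
#' Writes an [EEGRecording-class] as a plain EDF file with one-second data
#' records and per-signal linear calibration spanning the observed amplitude
#' range. The sampling rate must be an integer. Quantization to the 16-bit
#' digital range bounds the round-trip error at about 1/65000 of the signal
#' range.
#'
#' @param rec an [EEGRecording-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(rec@data)
  nFull <- floor(ncol(rec@data) / fs)
  if (nFull < 1) stop("recording shorter than one EDF data record")
  x <- rec@data[, seq_len(nFull * fs), drop = FALSE]
  physMin <- apply(x, 1, min); physMax <- apply(x, 1, max)
  same <- physMax - physMin < 1e-12
  physMax[same] <- physMin[same] + 1
  digMin <- -32768; digMax <- 32767
  gain <- (physMax - physMin) / (digMax - digMin)
  dig <- round(sweep(sweep(x, 1, physMin), 1, gain, "/") + digMin)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(v, w) writeChar(paste(vapply(v, padField, "", width = w),
                                        collapse = ""), con, eos = NULL)
  put("0", 8)
  put("X X X X", 80); put("Startdate X X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8)
  put("", 44)
  put(nFull, 8); put("1", 8); put(ns, 4)
  put(rownames(x), 16)
  put(rep("", ns), 80)
  put(rep("uV", ns), 8)
  put(formatC(physMin, digits = 7, format = "g"), 8)
  put(formatC(physMax, digits = 7, format = "g"), 8)
  put(rep(digMin, ns), 8); put(rep(digMax, ns), 8)
  put(rep("", ns), 80)
  put(rep(fs, ns), 8)
  put(rep("", ns), 32)
  for (r in seq_len(nFull)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
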