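sine <- function(f, fs, seconds = 4, amp = 1) {
  amp * sin(2 * pi * f * (0:(fs * seconds - 1)) / fs)
}
asRec <- function(x, fs, nch = 1, mains = 50) {
  data <- matrix(rep(x, each = nch), nrow = nch)
  rownames(data) <- paste0("CH", seq_len(nch))
  EEGRecording(data, fs = fs, mainsHz = mains)
}
rms <- function(x) sqrt(mean(x^2))

test_that("notch filter removes mains and passes the EEG band", {
  rec50 <- asRec(sine(50, 256, seconds = 16), 256)
  out <- notchFilter(rec50)
  mid <- 1025:3072  # steady-state region, away from filter edges
  expect_lt(rms(eegData(out)[1, mid]), 0.05 * rms(eegData(rec50)[1, mid]))
  rec10 <- asRec(sine(10, 256), 256)
  out10 <- notchFilter(rec10)
  mid <- 257:768  # ignore filter edges
  expect_lt(abs(rms(eegData(out10)[1, mid]) / rms(eegData(rec10)[1, mid]) - 1),
            0.02)
  z <- notchFilter(asRec(rep(0, 1024), 256))
  expect_equal(max(abs(eegData(z))), 0)
  expect_error(notchFilter(asRec(sine(5, 64), 64)), "notch")
})

test_that("high-pass removes DC and drift, passes 8 Hz", {
  dc <- asRec(rep(50, 256 * 16), 256)
  out <- highpassFilter(dc)
  expect_lt(mean(abs(eegData(out)[1, 1025:3072])), 0.5)
  drift <- sine(0.1, 256, seconds = 40)
  outd <- highpassFilter(asRec(drift, 256))
  mid <- 2561:7680
  att <- 20 * log10(rms(eegData(outd)[1, mid]) / rms(drift[mid]))
  expect_lt(att, -30)
  x8 <- sine(8, 256, seconds = 8)
  out8 <- highpassFilter(asRec(x8, 256))
  mid <- 513:1536
  expect_lt(abs(rms(eegData(out8)[1, mid]) / rms(x8[mid]) - 1), 0.02)
})

test_that("resampling to 128 Hz preserves duration and waveform", {
  rec <- asRec(sine(5, 256, seconds = 60), 256)
  out <- resampleTo128(rec)
  expect_equal(samplingRate(out), 128)
  expect_equal(ncol(eegData(out)), 60 * 128)
  # identity at 128 Hz
  rec128 <- asRec(sine(5, 128), 128)
  expect_equal(eegData(resampleTo128(rec128)), eegData(rec128))
  expect_error(resampleTo128(asRec(sine(5, 100), 100)), "128")
  # waveform fidelity from 512 Hz against the analytic 128 Hz samples
  out512 <- resampleTo128(asRec(sine(5, 512, seconds = 8), 512))
  ref <- sine(5, 128, seconds = 8)
  mid <- 65:960
  expect_gt(stats::cor(eegData(out512)[1, mid], ref[mid]), 0.999)
})

test_that("common average reference zeroes the cross-channel mean", {
  set.seed(3)
  data <- matrix(rnorm(4 * 512), 4, dimnames = list(paste0("CH", 1:4), NULL))
  rec <- EEGRecording(data, fs = 128)
  out <- commonAverageReference(rec)
  expect_lt(max(abs(colSums(eegData(out)))), 1e-9)
  # idempotent
  out2 <- commonAverageReference(out)
  expect_lt(max(abs(eegData(out2) - eegData(out))), 1e-12)
  # channels [a, -a] already reference-free
  pair <- EEGRecording(rbind(CH1 = data[1, ], CH2 = -data[1, ]), fs = 128)
  expect_equal(eegData(commonAverageReference(pair))[1, ], data[1, ])
  expect_error(commonAverageReference(asRec(rnorm(128), 128)), "2 channels")
})

test_that("epoching yields floor(n/256) epochs of exactly 256 samples", {
  mk <- function(n) EEGRecording(matrix(rnorm(n), 1,
                                        dimnames = list("CH1", NULL)),
                                 fs = 128)
  expect_length(segmentEpochs(mk(60 * 128)), 30)
  expect_length(segmentEpochs(mk(255)), 0)
  segs <- segmentEpochs(mk(512 + 100))
  expect_length(segs, 2)
  expect_true(all(vapply(segs, ncol, 0L) == 256))
})

test_that("artifact rejection uses a strict 100 uV bound and conserves count", {
  mk <- function(peak) {
    m <- matrix(0, 2, 256); m[1, 100] <- peak
    m
  }
  eps <- list(mk(101), mk(100), mk(0), mk(-150))
  out <- rejectArtifacts(eps)
  expect_equal(out$nRejected, 2)           # 101 and -150 rejected
  expect_length(out$kept, 2)
  expect_equal(length(eps), length(out$kept) + out$nRejected)
  expect_equal(out$kept[[1]][1, 100], 100) # boundary kept, order preserved
})

test_that("rating binarization uses the scale midpoint with >= convention", {
  expect_equal(binarizeRatings(2.5, 1, 5), 1L)
  expect_equal(binarizeRatings(2.4, 1, 5), 0L)
  expect_equal(binarizeRatings(4.5, 1, 9), 1L)
  expect_equal(binarizeRatings(c(1, 9), 1, 9), c(0L, 1L))
  expect_identical(binarizeRatings(c(0, 1, 1), 0, 1), c(0L, 1L, 1L))
  expect_error(binarizeRatings(9.5, 1, 9), "scale")
})

test_that("the conditioning chain runs in the fixed stage order", {
  pp <- preprocessRecording(toyRecording())
  expect_identical(pp$log, c("notch", "highpass", "resample", "car",
                             "epoch", "reject"))
})
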