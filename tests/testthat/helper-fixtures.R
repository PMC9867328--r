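# shared fixtures, built in code

# a small raw recording with known content
toyRecording <- function(nChannels = 2, fs = 256, seconds = 4,
                         f = 10, amp = 20, seed = 1) {
  set.seed(seed)
  t <- (0:(fs * seconds - 1)) / fs
  data <- t(vapply(seq_len(nChannels), function(i)
    amp * sin(2 * pi * f * t + i) + rnorm(length(t)), numeric(length(t))))
  rownames(data) <- paste0("CH", seq_len(nChannels))
  EEGRecording(data, fs = fs)
}

# labeled epochs whose classes differ in fractality (fBm Hurst exponent)
fractalEpochs <- function(nPerClass = 20, nChannels = 2,
                          hurst = c(0.45, 0.7), seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  arr <- array(0, dim = c(n, nChannels, 256),
               dimnames = list(NULL, paste0("CH", seq_len(nChannels)), NULL))
  labs <- rep(0:1, each = nPerClass)
  for (e in seq_len(n)) for (c in seq_len(nChannels))
    arr[e, c, ] <- genFBM(hurst[labs[e] + 1], 256)
  EEGEpochs(arr, labels = labs, dimension = "valence",
            subjectId = "S01",
            trialId = sprintf("T%02d", rep(seq_len(n / 4), length.out = n)))
}

# pure-noise features with optional label-copy canary column
nullFeatureMatrix <- function(n = 200, p = 10, canary = FALSE, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(0:1, length.out = n)
  if (canary) x <- cbind(x, canary = y)
  list(x = x, y = y)
}
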