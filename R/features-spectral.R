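#' The 12-scale Morlet pseudo-frequency ladder
#'
#' Centre frequencies (Hz) of the 12 wavelet scales used for the wavelet
#' feature set at 128 Hz: a near-geometric ladder (ratio about 1.402) from
#' 61.115 Hz down to 1.48 Hz, keeping every scale above 1.25 Hz.
#'
#' @return Numeric vector of 12 strictly decreasing frequencies in Hz.
#' @export
morletLadder <- function() {
  c(61.115, 43.59, 31.09, 22.17, 15.81, 11.28, 8.04,
    5.74, 4.09, 2.92, 2.08, 1.48)
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' FFT-based CWT of a 256-sample epoch with the analytic Morlet wavelet
#' (centre angular frequency `omega0 = 6`), evaluated at the scales whose
#' pseudo-frequencies form the [morletLadder()]. The transform uses L1
#' normalization (1/|a|), so a tone's coefficient magnitude is independent of
#' scale width.
#'
#' @param x numeric vector of 256 samples at `fs` Hz.
#' @param fs sampling rate in Hz.
#' @param frequencies pseudo-frequencies of the scales, in Hz.
#' @param omega0 Morlet centre angular frequency (rad/sample at scale 1).
#' @return Complex matrix scales x time (12 x 256) with attributes
#'   `frequencies` and `fs`.
#' @examples
#' C <- cwtMorlet(sin(2 * pi * 8.04 * (0:255) / 128))
#' which.max(rowMeans(Mod(C)))  # the 8.04 Hz scale
#' @export
cwtMorlet <- function(x, fs = 128, frequencies = morletLadder(), omega0 = 6) {
  if (length(x) != 256) stop("expected a 256-sample epoch")
  if (any(diff(frequencies) >= 0)) stop("frequencies must be decreasing")
  N <- length(x)
  X <- fft(x)
  w <- 2 * pi * (0:(N - 1)) / N
  w[w > pi] <- w[w > pi] - 2 * pi          # angular frequency per sample
  fc <- omega0 / (2 * pi)                  # Morlet centre frequency
  out <- matrix(0 + 0i, length(frequencies), N)
  for (i in seq_along(frequencies)) {
    a <- fc * fs / frequencies[i]          # scale in samples
    psiHat <- pi^(-0.25) * exp(-((a * w - omega0)^2) / 2) * (w > 0)
    out[i, ] <- fft(X * Conj(psiHat), inverse = TRUE) / N
  }
  structure(out, frequencies = frequencies, fs = fs)
}

#' Wavelet features: per-scale mean and SD of |coefficients|
#'
#' For each of the 12 scales, the mean and the population standard deviation
#' of the absolute wavelet coefficients across time, giving 24 features.
#'
#' @param C scaleogram from [cwtMorlet()].
#' @return Named numeric vector of length 24:
#'   `wav_mu_s01..wav_mu_s12, wav_sd_s01..wav_sd_s12`.
#' @export
waveletFeatures <- function(C) {
  A <- Mod(C)
  mu <- rowMeans(A)
  sdv <- sqrt(rowMeans((A - mu)^2))
  k <- sprintf("s%02d", seq_len(nrow(A)))
  stats::setNames(c(mu, sdv), c(paste0("wav_mu_", k), paste0("wav_sd_", k)))
}

#' Bispectrum on the principal domain
#'
#' Direct bispectrum estimate of an epoch:
#' `Bis(f1, f2) = E[X(f1) X(f2) X*(f1 + f2)]` where `X` is the FFT of each
#' (rectangular-windowed) segment and the expectation averages over segments.
#' Values are evaluated on the principal domain
#' `0 <= f2 <= f1, f1 + f2 <= fs/2` only. With the default single segment the
#' expectation is over one full-epoch FFT; averaging across realizations (sum
#' the `bis` matrices of independent epochs) sharpens phase-coupling
#' detection.
#'
#' @param x numeric vector of 256 samples.
#' @param nSegments 1, 2 or 4 segments to average over.
#' @param fs sampling rate in Hz.
#' @return A list of class `"BispectrumGrid"`: `bis` (complex matrix indexed
#'   by f1 x f2 bins, NA off the principal domain), `freqs` (bin frequencies,
#'   Hz), `mask` (logical principal-domain membership).
#' @examples
#' g <- bispectrum(genQPC(10, 21, 128, 256, coupled = TRUE, seed = 1))
#' @export
bispectrum <- function(x, nSegments = 1, fs = 128) {
  if (length(x) != 256) stop("expected a 256-sample epoch")
  if (!nSegments %in% c(1, 2, 4)) stop("nSegments must be 1, 2 or 4")
  L <- length(x) / nSegments
  nyq <- L / 2
  k <- 0:nyq
  mask <- outer(k, k, function(i, j) j <= i & i + j <= nyq)
  acc <- matrix(0 + 0i, nyq + 1, nyq + 1)
  for (s in seq_len(nSegments)) {
    X <- fft(x[((s - 1) * L + 1):(s * L)])
    acc <- acc + outer(k, k, function(i, j)
      X[i + 1] * X[j + 1] * Conj(X[i + j + 1]))
  }
  bis <- acc / nSegments
  bis[!mask] <- NA
  structure(list(bis = bis, freqs = k * fs / L, mask = mask),
            class = "BispectrumGrid")
}

#' Higher-order-spectra features from a bispectrum grid
#'
#' Four summaries of the bispectrum over the principal domain: the mean
#' magnitude (`hos_bismag`), the sum of log magnitudes (`hos_h1`), the sum of
#' log magnitudes along the diagonal `f1 = f2` (`hos_h2`), and the
#' first-order spectral moment of the diagonal log magnitudes (`hos_h3`,
#' weights being the 1-based diagonal bin index). A floor of 1e-12 inside
#' every logarithm keeps the sums finite for near-zero bins.
#'
#' @param g a `"BispectrumGrid"` from [bispectrum()], or the complex-mean of
#'   several such grids' `bis` matrices wrapped back into a grid.
#' @param eps log floor.
#' @return Named numeric vector: `hos_bismag, hos_h1, hos_h2, hos_h3`.
#' @export
hosFeatures <- function(g, eps = 1e-12) {
  stopifnot(inherits(g, "BispectrumGrid"))
  mag <- Mod(g$bis[g$mask])
  nd <- sum(diag(g$mask))
  dmag <- Mod(diag(g$bis))[seq_len(nd)]
  c(hos_bismag = mean(mag),
    hos_h1 = sum(log(pmax(mag, eps))),
    hos_h2 = sum(log(pmax(dmag, eps))),
    hos_h3 = sum(seq_len(nd) * log(pmax(dmag, eps))))
}
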