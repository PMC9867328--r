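#' Fractional Brownian motion by circulant embedding
#'
#' Generates an exact-covariance fractional Brownian motion (fBm) path: a
#' fractional Gaussian noise (fGn) sequence is drawn by circulant embedding of
#' the fGn autocovariance (Dietrich-Newsam), then cumulated. The path has
#' theoretical fractal dimension `2 - hurst`, which makes it the reference
#' signal for validating fractal-dimension estimators.
#'
#' @param hurst Hurst exponent in (0, 1); 0.5 is ordinary Brownian motion.
#' @param n number of samples (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `n`, starting at 0; increments have unit
#'   variance.
#' @examples
#' x <- genFBM(0.7, 512, seed = 1)
#' higuchiFD(x)  # close to 2 - 0.7
#' @export
genFBM <- function(hurst, n, seed = NULL) {
  c(0, cumsum(genFGN(hurst, n - 1, seed)))
}

# exact-covariance fGn: circulant embedding of the fGn autocovariance
genFGN <- function(hurst, n, seed = NULL) {
  if (length(hurst) != 1L || !is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly inside (0, 1)")
  if (n < 1) stop("n too small")
  H2 <- 2 * hurst
  m <- 2^ceiling(log2(max(2 * n, 8)))
  k <- 0:(m / 2)
  g <- 0.5 * ((k + 1)^H2 - 2 * k^H2 + abs(k - 1)^H2)
  crow <- c(g, g[(m / 2):2])
  ev <- Re(fft(crow))
  ev[ev < 0] <- 0  # guard against tiny negative eigenvalues
  if (!is.null(seed)) set.seed(seed)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(ev) * z))[seq_len(n)] / sqrt(m)
}

#' Weierstrass function with known box dimension
#'
#' Partial sum of the Weierstrass series
#' \eqn{W(t) = \sum_k a^k \cos(b^k \pi t)} on \eqn{t \in [0, 1]}, whose graph
#' has box-counting dimension \eqn{D = 2 + \ln a / \ln b} when \eqn{ab > 1}.
#' Serves as a closed-form oracle for fractal-dimension estimators.
#'
#' @param a amplitude decay in (0, 1).
#' @param b frequency growth (> 1), with `a * b > 1`.
#' @param nTerms number of series terms.
#' @param n number of samples on `[0, 1]`.
#' @return Numeric vector of length `n` with attribute `dimension`, the
#'   theoretical box dimension.
#' @examples
#' w <- genWeierstrass(0.5, 4, nTerms = 30, n = 4096)
#' attr(w, "dimension")  # 1.5
#' @export
genWeierstrass <- function(a, b, nTerms = 30, n = 4096) {
  if (a <= 0 || a >= 1 || b <= 1) stop("need 0 < a < 1 and b > 1")
  if (a * b <= 1) stop("need a * b > 1 for a fractal graph")
  t <- seq(0, 1, length.out = n)
  w <- numeric(n)
  for (k in 0:(nTerms - 1)) w <- w + a^k * cos(b^k * pi * t)
  attr(w, "dimension") <- 2 + log(a) / log(b)
  w
}

#' Quadratic-phase-coupled test signal
#'
#' Three cosines at `f1`, `f2` and `f1 + f2` with random phases. When
#' `coupled`, the third phase equals the sum of the first two, producing
#' quadratic phase coupling that the bispectrum detects at the bin pair
#' (`f1`, `f2`); otherwise all three phases are independent, so the bispectrum
#' averages toward zero across realizations.
#'
#' @param f1,f2 component frequencies in Hz; `f1 + f2` must stay below the
#'   Nyquist frequency.
#' @param fs sampling rate in Hz.
#' @param n number of samples.
#' @param coupled logical; plant quadratic phase coupling?
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param noiseSd standard deviation of additive Gaussian noise.
#' @param amplitude amplitude of each cosine.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- genQPC(10, 21, fs = 128, n = 256, coupled = TRUE, seed = 1)
#' @export
genQPC <- function(f1, f2, fs, n, coupled = TRUE, seed = NULL,
                   noiseSd = 0.1, amplitude = 1) {
  if (f1 <= 0 || f2 <= 0 || f1 + f2 >= fs / 2)
    stop("need 0 < f1, f2 and f1 + f2 < fs/2 (aliasing)")
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(n - 1)) / fs
  p1 <- runif(1, 0, 2 * pi)
  p2 <- runif(1, 0, 2 * pi)
  p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
  amplitude * (cos(2 * pi * f1 * t + p1) + cos(2 * pi * f2 * t + p2) +
               cos(2 * pi * (f1 + f2) * t + p3)) + noiseSd * rnorm(n)
}
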