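## Fractal-dimension estimators: Katz, Petrosian, Higuchi. All three are
## affine-invariant (unchanged under a*x + c) and return 1 for smooth or
## degenerate inputs.

#' Katz fractal dimension
#'
#' Katz's waveform estimator on the unit-abscissa convention: curve length
#' `L` is the sum of absolute successive differences, diameter `d` the
#' maximum distance from the first point, and the step count `n = T - 1`
#' normalizes both, giving `KFD = log(n) / (log(n) + log(d/L))`. A constant
#' signal (zero length or diameter) returns 1.
#'
#' @param x numeric vector (length >= 3).
#' @return Katz fractal dimension, >= 1.
#' @examples
#' katzFD(c(0, 2, 1))  # about 2.409
#' @export
katzFD <- function(x) {
  T <- length(x)
  if (T < 3) stop("need at least 3 samples")
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(1)
  n <- T - 1
  log(n) / (log(n) + log(d / L))
}

#' Petrosian fractal dimension
#'
#' Converts the series into the sign sequence of its first differences and
#' counts sign changes `Ndelta` between consecutive non-zero signs (zero
#' differences continue the previous sign). With `m` the series length,
#' `PFD = log(m) / (log(m) + log(m / (m + 0.4 Ndelta)))`. A monotone or
#' constant series returns 1.
#'
#' @param x numeric vector (length >= 3).
#' @return Petrosian fractal dimension, >= 1.
#' @examples
#' petrosianFD(c(0, 1, 0, 1, 0))  # about 1.154
#' @export
petrosianFD <- function(x) {
  m <- length(x)
  if (m < 3) stop("need at least 3 samples")
  s <- sign(diff(x))
  s <- s[s != 0]
  nd <- if (length(s) > 1) sum(diff(s) != 0) else 0
  if (nd == 0) return(1)
  log(m) / (log(m) + log(m / (m + 0.4 * nd)))
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension from the scaling of the mean curve length
#' `L(j)` of lag-`j` subsampled series: for each lag `j = 1..kmax` and offset
#' `i = 1..j` the normalized length `L_i(j)` is computed, averaged over
#' offsets, and the least-squares slope of `log L(j)` against `log(1/j)` is
#' returned. Values near 1 indicate a smooth curve, near 2 a plane-filling
#' (white-noise-like) one; fBm with Hurst exponent H yields approximately
#' `2 - H`.
#'
#' @param x numeric vector with `length(x) >= 4 * kmax`.
#' @param kmax maximum lag (default 10).
#' @return Higuchi fractal dimension.
#' @examples
#' higuchiFD(genFBM(0.5, 2048, seed = 1))  # about 1.5
#' @export
higuchiFD <- function(x, kmax = 10) {
  N <- length(x)
  if (kmax < 2) stop("kmax must be at least 2")
  if (N < 4 * kmax) stop("series too short for kmax = ", kmax)
  Lj <- numeric(kmax)
  for (j in seq_len(kmax)) {
    d <- abs(x[(j + 1):N] - x[1:(N - j)])        # |x(t+j) - x(t)| for all t
    grp <- (seq_along(d) - 1L) %% j              # offset i-1 of each term
    sums <- rowsum(d, grp)                       # per-offset length sums
    nm <- tabulate(grp + 1L, nbins = j)          # terms per offset
    Lj[j] <- mean(sums * (N - 1) / (nm * j) / j)
  }
  lx <- log(1 / seq_len(kmax)); ly <- log(Lj)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}
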