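## Time-domain per-channel epoch features: descriptive statistics and Hjorth
## parameters. All moments use the population (1/T) normalization, applied
## consistently to SD, skewness, kurtosis and the Hjorth derivative SDs.

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Statistical features of a single-channel epoch
#'
#' Nine descriptive statistics of the raw time series: mean, median,
#' population standard deviation, skewness, kurtosis (non-excess convention,
#' Gaussian = 3), mean absolute first and second difference, and the two
#' differences normalized by the standard deviation. For a constant epoch
#' (zero SD) the normalized differences, skewness and kurtosis are defined as
#' 0 so that downstream classifiers never see missing values; a warning is
#' emitted.
#'
#' @param x numeric vector, one channel of one epoch (length >= 3).
#' @return Named numeric vector of length 9:
#'   `stat_mean, stat_median, stat_std, stat_skew, stat_kurt, stat_d1,
#'   stat_d2, stat_nd1, stat_nd2`.
#' @examples
#' statisticalFeatures(c(0, 1, 0, 1))
#' @export
statisticalFeatures <- function(x) {
  T <- length(x)
  if (T < 3) stop("epoch too short (need at least 3 samples)")
  mu <- mean(x)
  sdev <- popSd(x)
  d1 <- mean(abs(diff(x)))
  d2 <- mean(abs(x[3:T] - x[1:(T - 2)]))
  if (sdev > 0) {
    z <- (x - mu) / sdev
    skew <- mean(z^3); kurt <- mean(z^4)
    nd1 <- d1 / sdev; nd2 <- d2 / sdev
  } else {
    warning("zero-variance epoch: normalized statistics set to 0")
    skew <- kurt <- nd1 <- nd2 <- 0
  }
  c(stat_mean = mu, stat_median = median(x), stat_std = sdev,
    stat_skew = skew, stat_kurt = kurt,
    stat_d1 = d1, stat_d2 = d2, stat_nd1 = nd1, stat_nd2 = nd2)
}

#' Hjorth mobility and complexity
#'
#' Mobility is the ratio of the standard deviation of the first difference to
#' that of the signal, an estimate of mean frequency; complexity is the
#' mobility of the first difference divided by the mobility of the signal, an
#' estimate of bandwidth. Derivatives are one-step finite differences of the
#' discrete series (no division by the sampling interval; complexity is
#' unaffected and mobility only rescaled uniformly). A zero-variance epoch
#' yields 0 for both.
#'
#' @param x numeric vector, one channel of one epoch (length >= 3).
#' @return Named numeric vector: `hjorth_mobility`, `hjorth_complexity`.
#' @examples
#' hjorthParameters(sin(2 * pi * 8 * (0:255) / 128))
#' @export
hjorthParameters <- function(x) {
  if (length(x) < 3) stop("epoch too short (need at least 3 samples)")
  sx <- popSd(x)
  if (sx == 0) {
    warning("zero-variance epoch: Hjorth parameters set to 0")
    return(c(hjorth_mobility = 0, hjorth_complexity = 0))
  }
  d <- diff(x); dd <- diff(d)
  sd1 <- popSd(d); sd2 <- popSd(dd)
  h1 <- sd1 / sx
  h2 <- if (sd1 > 0) (sd2 / sd1) / h1 else 0
  c(hjorth_mobility = h1, hjorth_complexity = h2)
}
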