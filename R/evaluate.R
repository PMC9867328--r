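#' Two-tailed paired t-test on per-subject accuracies
#'
#' Paired t on the subject-wise differences, with explicit handling of the
#' degenerate zero-variance case rather than a division by zero: if every
#' difference is exactly zero the test is reported as t = 0, p = 1; if the
#' differences are constant but non-zero the evidence is one-sided and
#' unbounded, reported as infinite t with p = 0, flagged degenerate.
#'
#' @param a,b equal-length numeric vectors paired by subject (length >= 3).
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1,
                                 degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down family-wise error correction with monotonicity enforcement and
#' capping at 1; order of the input is preserved.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holmBonferroni(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmBonferroni <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Cliff's delta effect size
#'
#' Non-parametric effect size in [-1, 1]: the difference between the
#' proportion of pairs in which `a` exceeds `b` and the proportion in which
#' `b` exceeds `a`, computed by brute force over all pairs. +1/-1 indicate
#' complete separation; 0 indicates full overlap.
#'
#' @param a,b non-empty numeric vectors.
#' @return Cliff's delta.
#' @examples
#' cliffsDelta(c(1, 3), c(2, 4))  # -0.5
#' @export
cliffsDelta <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input")
  s <- outer(a, b, function(x, y) sign(x - y))
  sum(s) / (length(a) * length(b))
}

#' Compare feature sets against a reference set
#'
#' For each non-reference feature set, runs a two-tailed paired t-test of the
#' per-subject mean accuracies (reference minus other), applies the
#' Holm-Bonferroni correction across the family of comparisons, and computes
#' Cliff's delta on the paired accuracy vectors.
#'
#' @param results long-format data.frame from [subjectCV()] (columns subject,
#'   featureSet, classifier, mean).
#' @param reference name of the reference feature set (default `"fractal"`).
#' @param classifier restrict the comparison to one classifier.
#' @return data.frame of class `"ComparisonResult"` with columns pair,
#'   classifier, t, p_raw, p_holm, cliffs_delta, n_subjects.
#' @export
compareFeatureSets <- function(results, reference = "fractal",
                               classifier = "cart") {
  res <- results[results$classifier == classifier, ]
  sets <- setdiff(unique(res$featureSet), reference)
  if (!length(sets)) stop("nothing to compare against ", reference)
  ref <- res[res$featureSet == reference, c("subject", "mean")]
  out <- NULL
  for (fs in sets) {
    oth <- res[res$featureSet == fs, c("subject", "mean")]
    merged <- merge(ref, oth, by = "subject", suffixes = c("_ref", "_oth"))
    missing <- setdiff(union(ref$subject, oth$subject), merged$subject)
    if (length(missing))
      stop("subjects missing one of the pair ", reference, " vs ", fs, ": ",
           paste(missing, collapse = ", "))
    tt <- pairedTTest(merged$mean_ref, merged$mean_oth)
    out <- rbind(out, data.frame(
      pair = paste(reference, "vs", fs), classifier = classifier,
      t = tt$t, p_raw = tt$p,
      cliffs_delta = cliffsDelta(merged$mean_ref, merged$mean_oth),
      n_subjects = nrow(merged)))
  }
  out$p_holm <- holmBonferroni(out$p_raw)
  out <- out[, c("pair", "classifier", "t", "p_raw", "p_holm",
                 "cliffs_delta", "n_subjects")]
  class(out) <- c("ComparisonResult", "data.frame")
  out
}

#' Channel topography export
#'
#' Z-scores one per-channel feature over all epochs (mean 0, SD 1 before any
#' class split), averages within the high and low label groups, and restricts
#' the result to the 14 shared montage channels. The output is the
#' channel:value table a scalp-map plotting layer consumes.
#'
#' @param features an [EEGFeatures-class] object.
#' @param feature base feature name, e.g. `"fd_higuchi"`.
#' @param channels channels to report (default [epocChannels()]).
#' @return data.frame with columns channel, class (`"high"`/`"low"`), z.
#' @export
topographyExport <- function(features, feature, channels = epocChannels()) {
  stopifnot(is(features, "EEGFeatures"))
  rd <- SummarizedExperiment::rowData(features)
  have <- rd$channel[rd$feature == feature]
  miss <- setdiff(channels, have)
  if (length(miss))
    stop("channels missing from the table: ", paste(miss, collapse = ", "))
  lab <- epochLabels(features)
  out <- NULL
  for (ch in channels) {
    v <- SummarizedExperiment::assay(features, "features")[
      which(rd$feature == feature & rd$channel == ch)[1], ]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constant feature on channel ", ch, "; z-scores set to 0")
      z <- rep(0, length(v))
    } else z <- (v - mean(v)) / s
    out <- rbind(out,
                 data.frame(channel = ch, class = "high",
                            z = mean(z[lab == 1])),
                 data.frame(channel = ch, class = "low",
                            z = mean(z[lab == 0])))
  }
  out
}
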