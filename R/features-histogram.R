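#' First-order (histogram) intensity features
#'
#' Ten statistics of the in-mask intensity distribution.  Energy and
#' entropy are computed on the normalized 64-bin equal-width histogram of
#' in-mask intensities (entropy in bits); the remaining statistics are
#' computed on the raw values.  A constant ROI has entropy 0, energy 1 and
#' SD/skewness/kurtosis 0 by convention.
#'
#' @param img a [lesion_image()].
#' @param bins number of histogram bins for energy/entropy.
#' @return named numeric vector of length 10: `hist_mean`, `hist_sd`,
#'   `hist_skewness`, `hist_kurtosis`, `hist_median`, `hist_iqr`,
#'   `hist_min`, `hist_max`, `hist_energy`, `hist_entropy`.
#' @export
histogram_features <- function(img, bins = 64L) {
  stopifnot(inherits(img, "lesion_image"))
  v <- img$intensity[img$mask]
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sdev <- sqrt(m2 * n / max(1, n - 1))
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  p <- roi_histogram(v, bins)
  c(hist_mean = m,
    hist_sd = sdev,
    hist_skewness = skew,
    hist_kurtosis = kurt,
    hist_median = stats::median(v),
    hist_iqr = unname(stats::quantile(v, 0.75) - stats::quantile(v, 0.25)),
    hist_min = min(v),
    hist_max = max(v),
    hist_energy = sum(p^2),
    hist_entropy = entropy_bits(p))
}

# normalized equal-width histogram over [min, max]; constant -> single bin
roi_histogram <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(1)
  idx <- pmin.int(floor((v - lo) / (hi - lo) * bins) + 1L, as.integer(bins))
  tabulate(idx, nbins = bins) / length(v)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
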