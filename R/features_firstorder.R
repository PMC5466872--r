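# First-order (intensity) statistics of the in-mask voxel values.
# Conventions pinned for reproducibility:
#   * variance/SD divide by N (population);
#   * skewness = m3 / m2^1.5 and kurtosis = m4 / m2^2 (uncorrected,
#     normal -> 3), both 0 by convention when the region is constant;
#   * percentiles by linear interpolation between order statistics;
#   * histogram entropy/uniformity use the same uniform binning as the
#     texture quantization (n_levels bins over the in-mask range).

.FIRST_ORDER_NAMES <- c(
  "fo_mean", "fo_median", "fo_minimum", "fo_maximum", "fo_range",
  "fo_interquartile_range", "fo_percentile10", "fo_percentile90",
  "fo_variance", "fo_standard_deviation", "fo_mean_absolute_deviation",
  "fo_robust_mean_absolute_deviation", "fo_root_mean_square", "fo_energy",
  "fo_total_energy", "fo_skewness", "fo_kurtosis", "fo_entropy",
  "fo_uniformity")

#' First-order intensity features
#'
#' Computes the 19 first-order statistics of the in-mask intensities:
#' location (mean, median, percentiles), dispersion (variance, SD, MAD,
#' robust MAD, IQR, range), energy (sum of squares; total energy scales
#' by the voxel volume in mm^3), shape of the distribution (skewness,
#' kurtosis) and histogram summaries (entropy, uniformity) on the
#' quantized histogram.
#'
#' @param volume a [volume_grid()].
#' @param mask a non-empty [voi_mask()] on the same grid.
#' @param n_levels histogram bin count for entropy/uniformity
#'   (shared with [quantize()]); default 32.
#' @return Named numeric vector of the 19 first-order features.
#' @export
first_order_features <- function(volume, mask, n_levels = 32L) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "voi_mask"))
  check_geometry(mask, volume)
  if (!any(mask$voxels)) stop("empty mask: no first-order features")
  x <- volume$voxels[mask$voxels]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  trimmed <- x[x >= qs[1] & x <= qs[4]]
  vv <- voxel_volume(mask)

  qv <- quantize(volume, mask, n_levels = max(2L, as.integer(n_levels)))
  p <- tabulate(qv$levels[qv$levels > 0L], nbins = qv$n_levels) / n
  p <- p[p > 0]

  out <- c(
    fo_mean = mu,
    fo_median = median(x),
    fo_minimum = min(x),
    fo_maximum = max(x),
    fo_range = max(x) - min(x),
    fo_interquartile_range = qs[3] - qs[2],
    fo_percentile10 = qs[1],
    fo_percentile90 = qs[4],
    fo_variance = m2,
    fo_standard_deviation = sqrt(m2),
    fo_mean_absolute_deviation = mean(abs(x - mu)),
    fo_robust_mean_absolute_deviation =
      mean(abs(trimmed - mean(trimmed))),
    fo_root_mean_square = sqrt(mean(x^2)),
    fo_energy = sum(x^2),
    fo_total_energy = vv * sum(x^2),
    fo_skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2))
  out[.FIRST_ORDER_NAMES]
}
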