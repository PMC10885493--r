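# First-order (intensity histogram) features over the in-mask voxels.

#' First-order intensity statistics
#'
#' Statistics of the in-mask intensity distribution. `robust_mad` is the mean
#' absolute deviation from the mean computed on the values falling inside the
#' closed [10th, 90th] percentile range (robust mean absolute deviation).
#' Skewness and excess kurtosis of a constant region are defined as 0.
#'
#' @param volume an [image_volume()] (possibly filtered).
#' @param mask an aligned non-empty [voi_mask()].
#' @return Named numeric vector of features.
#' @export
firstorder_features <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  check_aligned(volume, mask)
  x <- volume$values[mask$values == 1L]
  if (length(x) == 0L) stop("mask is empty")
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)                      # population variance
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 - 3 else 0
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  robust_mad <- mean(abs(rob - mean(rob)))
  c(mean = m, variance = v, sd = s, skewness = skew, kurtosis = kurt,
    minimum = min(x), maximum = max(x), range = max(x) - min(x),
    percentile10 = q[1], percentile25 = q[2], median = q[3],
    percentile75 = q[4], percentile90 = q[5],
    interquartile_range = q[4] - q[2],
    mad = mean(abs(x - m)), robust_mad = robust_mad,
    energy = sum(x^2), rms = sqrt(mean(x^2)))
}
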