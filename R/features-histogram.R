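#' First-order (intensity histogram) features
#'
#' Computes the 16 first-order features of the in-mask intensity
#' distribution. Moments (variance, skewness, kurtosis) are population
#' moments; kurtosis is the non-excess Pearson form (`m4 / m2^2`, 3 for a
#' Gaussian). `entropy` (base 2), `uniformity` and `gray_level_count` are
#' computed on the discretized histogram (`n_bins` equal-width bins, as in
#' [discretize()]); the remaining features use the raw intensities.
#'
#' @param volume a [volume3d()].
#' @param mask a [lesion_mask()] on the same grid.
#' @param n_bins bins for the histogram-derived features (default 32).
#' @return Named numeric vector of length 16.
#' @export
histogram_features <- function(volume, mask, n_bins = 32L) {
  stopifnot(inherits(volume, "Volume3D"), inherits(mask, "LesionMask"))
  if (!grid_compatible(volume, mask)) stop("volume and mask grids differ")
  inmask <- mask$values == 1L
  if (!any(inmask)) stop("empty mask")
  x <- volume$values[inmask]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)

  region <- discretize(volume, mask, n_bins = n_bins)
  g <- region$levels[inmask]
  counts <- tabulate(g, nbins = region$n_levels)
  p <- counts[counts > 0] / n

  c(
    voxel_count = n,
    gray_level_count = sum(counts > 0),
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    maximum = max(x),
    mean = mu,
    median = stats::median(x),
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    root_mean_square = sqrt(mean(x^2)),
    standard_deviation = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2)
  )
}
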