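#' Discretize in-mask intensities into equal-width gray levels
#'
#' Bins the masked voxel intensities into `n_bins` equal-width bins over
#' `[min, max]` of the in-mask values; the maximum value falls in the top
#' bin. A constant region collapses to a single level (`G = 1`) and is
#' flagged degenerate.
#'
#' @param volume a [volume3d()].
#' @param mask a [lesion_mask()] on the same grid with at least one
#'   foreground voxel.
#' @param n_bins number of gray levels `G >= 2`.
#' @return A list of class `DiscretizedRegion`: `levels` (integer array,
#'   `NA` outside the mask, values `1..G` inside), `n_levels`, `bin_edges`,
#'   `degenerate` flag, and the `mask` dimensions.
#' @export
discretize <- function(volume, mask, n_bins = 32L) {
  stopifnot(inherits(volume, "Volume3D"), inherits(mask, "LesionMask"))
  if (!grid_compatible(volume, mask)) {
    stop("volume and mask grids differ")
  }
  inmask <- mask$values == 1L
  if (!any(inmask)) stop("empty mask")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  x <- volume$values[inmask]
  lo <- min(x)
  hi <- max(x)
  levels <- array(NA_integer_, dim = dim(volume$values))
  if (hi == lo) {
    levels[inmask] <- 1L
    return(structure(list(levels = levels, n_levels = 1L,
                          bin_edges = c(lo, hi), degenerate = TRUE),
                     class = "DiscretizedRegion"))
  }
  w <- (hi - lo) / n_bins
  g <- pmin(floor((x - lo) / w) + 1, n_bins)
  levels[inmask] <- as.integer(g)
  structure(list(levels = levels, n_levels = n_bins,
                 bin_edges = lo + w * (0:n_bins), degenerate = FALSE),
            class = "DiscretizedRegion")
}
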