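#' Seeded region-growing lesion segmentation
#'
#' Segments an enhancing lesion on a subtraction image by growing a
#' 26-connected region from a seed voxel. The inclusion threshold is
#' `grow_fraction` times the mean intensity of the seed's 3x3x3 neighborhood
#' (clipped at the grid boundary); the mask is the 26-connected component of
#' the seed among voxels with intensity at or above that threshold. Growth
#' halts once `max_voxels` voxels have been accepted, in which case the
#' returned mask carries attribute `truncated = TRUE` and a warning is
#' emitted.
#'
#' @param volume a [volume3d()] subtraction image.
#' @param seed_point integer length-3 voxel index (1-based `(i, j, k)`).
#' @param grow_fraction threshold fraction in `(0, 1]` of the seed
#'   neighborhood mean (default 0.5).
#' @param max_voxels growth cap (default `Inf`).
#' @return A [lesion_mask()] on the volume's grid, with attributes
#'   `threshold` (the absolute intensity cutoff used) and `truncated`.
#' @export
region_grow_segment <- function(volume, seed_point, grow_fraction = 0.5,
                                max_voxels = Inf) {
  stopifnot(inherits(volume, "Volume3D"))
  if (!(is.numeric(grow_fraction) && length(grow_fraction) == 1L &&
        grow_fraction > 0 && grow_fraction <= 1)) {
    stop("grow_fraction must lie in (0, 1]")
  }
  d <- dim(volume$values)
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) ||
      any(seed_point > d)) {
    stop("seed point (", paste(seed_point, collapse = ","),
         ") outside grid of dims ", paste(d, collapse = "x"))
  }
  lo <- pmax(seed_point - 1L, 1L)
  hi <- pmin(seed_point + 1L, d)
  neigh <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  seed_mean <- mean(neigh)
  if (seed_mean <= 0) {
    stop("no enhancement at seed: neighborhood mean intensity ",
         format(seed_mean), " <= 0")
  }
  threshold <- grow_fraction * seed_mean

  vals <- volume$values
  eligible <- vals >= threshold
  if (!eligible[seed_point[1], seed_point[2], seed_point[3]]) {
    # the seed voxel itself is always part of the region it defines
    eligible[seed_point[1], seed_point[2], seed_point[3]] <- TRUE
  }
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]

  visited <- array(FALSE, dim = d)
  visited[seed_point[1], seed_point[2], seed_point[3]] <- TRUE
  frontier <- matrix(seed_point, nrow = 1)
  n_accepted <- 1L
  truncated <- FALSE
  while (nrow(frontier) > 0L && n_accepted < max_voxels) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offsets)), ,
                     drop = FALSE] +
      offsets[rep(seq_len(nrow(offsets)), times = nrow(frontier)), ,
              drop = FALSE]
    keep <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
      cand[, 2] >= 1L & cand[, 2] <= d[2] &
      cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
    keep <- !visited[lin] & eligible[lin] & !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    lin <- lin[keep]
    if (length(lin) == 0L) break
    room <- max_voxels - n_accepted
    if (length(lin) > room) {
      cand <- cand[seq_len(room), , drop = FALSE]
      lin <- lin[seq_len(room)]
      truncated <- TRUE
    }
    visited[lin] <- TRUE
    n_accepted <- n_accepted + length(lin)
    frontier <- cand
  }
  if (is.finite(max_voxels) && n_accepted >= max_voxels) truncated <- TRUE
  if (truncated) {
    warning("region growing halted at max_voxels = ", max_voxels)
  }
  mask <- lesion_mask(visited, volume$spacing, volume$origin)
  attr(mask, "threshold") <- threshold
  attr(mask, "truncated") <- truncated
  mask
}
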