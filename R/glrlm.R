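#' Gray-level run-length matrix for one direction
#'
#' A run is a maximal collinear sequence of in-mask voxels sharing a gray
#' level along the given lattice direction. `R[g, l]` counts runs of level
#' `g` and length `l`; the conservation identity
#' `sum(l * R[g, l]) == in-mask voxel count` holds for every direction.
#'
#' @param region a `DiscretizedRegion` from [discretize()].
#' @param direction integer length-3 lattice step (one of
#'   [lattice_directions_3d()]).
#' @return A `G x L` integer matrix of run counts with attribute
#'   `direction`.
#' @export
compute_glrlm <- function(region, direction) {
  stopifnot(inherits(region, "DiscretizedRegion"))
  d <- as.integer(direction)
  stopifnot(length(d) == 3L, any(d != 0L))
  lv <- region$levels
  dims <- dim(lv)
  G <- region$n_levels
  inmask <- !is.na(lv)
  if (!any(inmask)) stop("empty mask")

  idx <- which(inmask, arr.ind = TRUE)
  lin_of <- function(m) m[, 1] + dims[1] * (m[, 2] - 1L) +
    dims[1] * dims[2] * (m[, 3] - 1L)
  in_grid <- function(m) {
    m[, 1] >= 1L & m[, 1] <= dims[1] &
      m[, 2] >= 1L & m[, 2] <= dims[2] &
      m[, 3] >= 1L & m[, 3] <= dims[3]
  }
  lvv <- as.vector(lv)

  # run starts: predecessor out of grid / out of mask / different level
  pred <- sweep(idx, 2, d, `-`)
  ok <- in_grid(pred)
  same <- rep(FALSE, nrow(idx))
  same[ok] <- !is.na(lvv[lin_of(pred[ok, , drop = FALSE])]) &
    lvv[lin_of(pred[ok, , drop = FALSE])] == lvv[lin_of(idx[ok, , drop = FALSE])]
  starts <- idx[!same, , drop = FALSE]
  start_level <- lvv[lin_of(starts)]

  # walk each run forward, all runs advanced in lockstep
  len <- rep(1L, nrow(starts))
  pos <- starts
  active <- seq_len(nrow(starts))
  while (length(active) > 0L) {
    nxt <- sweep(pos[active, , drop = FALSE], 2, d, `+`)
    ok <- in_grid(nxt)
    lev_next <- rep(NA_integer_, length(active))
    lev_next[ok] <- lvv[lin_of(nxt[ok, , drop = FALSE])]
    extend <- !is.na(lev_next) & lev_next == start_level[active]
    len[active[extend]] <- len[active[extend]] + 1L
    pos[active[extend], ] <- nxt[extend, , drop = FALSE]
    active <- active[extend]
  }

  L <- max(len)
  R <- matrix(0L, nrow = G, ncol = L)
  tab <- tabulate((start_level - 1L) * L + len, nbins = G * L)
  R <- matrix(tab, nrow = G, ncol = L, byrow = TRUE)
  attr(R, "direction") <- d
  R
}

#' Galloway-style run-length features
#'
#' Evaluates the standard 11-feature run-length set, normalizing by the
#' total run count `Nr`; `rp` (run percentage) is `Nr / n_voxels`.
#'
#' @param R run-count matrix from [compute_glrlm()] (rows = gray levels,
#'   columns = run lengths).
#' @param n_voxels in-mask voxel count for the run-percentage denominator.
#' @return Named numeric vector of length 11: `sre`, `lre`,
#'   `gray_level_nonuniformity`, `run_length_nonuniformity`, `rp`,
#'   `low_gray_run_emphasis`, `high_gray_run_emphasis`,
#'   `short_run_low_gray_emphasis`, `short_run_high_gray_emphasis`,
#'   `lrlgle`, `lrhgle`.
#' @export
glrlm_features <- function(R, n_voxels) {
  if (sum(R) == 0) stop("run-length matrix holds zero runs")
  G <- nrow(R)
  L <- ncol(R)
  g <- matrix(seq_len(G), G, L)
  l <- matrix(seq_len(L), G, L, byrow = TRUE)
  nr <- sum(R)
  c(
    sre = sum(R / l^2) / nr,
    lre = sum(R * l^2) / nr,
    gray_level_nonuniformity = sum(rowSums(R)^2) / nr,
    run_length_nonuniformity = sum(colSums(R)^2) / nr,
    rp = nr / n_voxels,
    low_gray_run_emphasis = sum(R / g^2) / nr,
    high_gray_run_emphasis = sum(R * g^2) / nr,
    short_run_low_gray_emphasis = sum(R / (g^2 * l^2)) / nr,
    short_run_high_gray_emphasis = sum(R * g^2 / l^2) / nr,
    lrlgle = sum(R * l^2 / g^2) / nr,
    lrhgle = sum(R * g^2 * l^2) / nr
  )
}
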