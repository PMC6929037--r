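#' The 13 unique 3D lattice directions
#'
#' Displacements at Chebyshev distance 1 covering each opposite pair once;
#' used for both co-occurrence and run-length texture.
#'
#' @return A 13 x 3 integer matrix of `(di, dj, dk)` steps.
#' @export
lattice_directions_3d <- function() {
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each (+d, -d) pair: first nonzero component positive
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  m <- d[keep, , drop = FALSE]
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix for one displacement
#'
#' Counts ordered in-mask voxel pairs `(x, x + d)` sharing the mask,
#' accumulates symmetrically (both `d` and `-d`), and normalizes to sum 1.
#' If the displacement yields no valid pair the matrix is returned as all
#' zeros with attribute `empty = TRUE`.
#'
#' @param region a `DiscretizedRegion` from [discretize()].
#' @param displacement integer length-3 voxel step.
#' @return A `G x G` matrix of co-occurrence probabilities with attributes
#'   `displacement` and `empty`.
#' @export
compute_glcm <- function(region, displacement) {
  stopifnot(inherits(region, "DiscretizedRegion"))
  d <- as.integer(displacement)
  stopifnot(length(d) == 3L, any(d != 0L))
  lv <- region$levels
  dims <- dim(lv)
  G <- region$n_levels
  a <- pmax(1L, 1L - d)
  b <- pmin(dims, dims - d)
  P <- matrix(0, G, G)
  if (all(a <= b)) {
    g1 <- lv[a[1]:b[1], a[2]:b[2], a[3]:b[3]]
    g2 <- lv[(a[1] + d[1]):(b[1] + d[1]),
             (a[2] + d[2]):(b[2] + d[2]),
             (a[3] + d[3]):(b[3] + d[3])]
    ok <- !is.na(g1) & !is.na(g2)
    if (any(ok)) {
      counts <- tabulate((g1[ok] - 1L) * G + g2[ok], nbins = G * G)
      C <- matrix(counts, G, G, byrow = TRUE)
      C <- C + t(C) # symmetric accumulation: d and -d
      P <- C / sum(C)
    }
  }
  attr(P, "displacement") <- d
  attr(P, "empty") <- sum(P) == 0
  P
}

#' Haralick-style co-occurrence features
#'
#' Evaluates the standard 21-feature set on a normalized, symmetric GLCM.
#' Gray-level indices run `1..G`. With a degenerate marginal (zero variance,
#' e.g. a constant region), `correlation`, `imc1` and `imc2` are returned as
#' `NaN` and the result carries attribute `degenerate = TRUE`.
#'
#' Sum/difference distributions: `p_{x+y}(k) = sum_{i+j=k} P(i,j)` for
#' `k = 2..2G` and `p_{x-y}(k) = sum_{|i-j|=k} P(i,j)` for `k = 0..G-1`.
#' `sum_variance` is the variance of `p_{x+y}` about `sum_average`;
#' `difference_variance` the variance of `p_{x-y}` about its mean. All
#' entropies are base 2.
#'
#' @param P normalized GLCM from [compute_glcm()].
#' @return Named numeric vector of length 21.
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  lv <- seq_len(G)
  mu_x <- sum(lv * px)
  mu_y <- sum(lv * py)
  sig_x <- sqrt(sum((lv - mu_x)^2 * px))
  sig_y <- sqrt(sum((lv - mu_y)^2 * py))

  # sum and difference distributions
  ipj <- i + j
  imj <- abs(i - j)
  p_sum <- vapply(2:(2 * G), function(k) sum(P[ipj == k]), numeric(1))
  k_sum <- 2:(2 * G)
  p_dif <- vapply(0:(G - 1), function(k) sum(P[imj == k]), numeric(1))
  k_dif <- 0:(G - 1)

  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pxpy <- outer(px, py)
  okxy <- nz & pxpy > 0
  hxy1 <- -sum(P[okxy] * log2(pxpy[okxy]))
  okp <- pxpy > 0
  hxy2 <- -sum(pxpy[okp] * log2(pxpy[okp]))

  degenerate <- sig_x == 0 || sig_y == 0
  autoc <- sum(i * j * P)
  sum_average <- sum(k_sum * p_sum)
  dif_average <- sum(k_dif * p_dif)
  psnz <- p_sum > 0
  pdnz <- p_dif > 0
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else NaN
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  out <- c(
    autocorrelation = autoc,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (degenerate) NaN else
      (autoc - mu_x * mu_y) / (sig_x * sig_y),
    difference_entropy = -sum(p_dif[pdnz] * log2(p_dif[pdnz])),
    dissimilarity = sum(imj * P),
    energy_asm = sum(P^2),
    entropy = entropy,
    homogeneity1 = sum(P / (1 + imj)),
    homogeneity2 = sum(P / (1 + imj^2)),
    imc1 = if (degenerate) NaN else imc1,
    imc2 = if (degenerate) NaN else imc2,
    inverse_variance = sum(P[imj > 0] / imj[imj > 0]^2),
    max_probability = max(P),
    sum_average = sum_average,
    sum_entropy = -sum(p_sum[psnz] * log2(p_sum[psnz])),
    sum_variance = sum((k_sum - sum_average)^2 * p_sum),
    variance = sum((i - mu_x)^2 * P),
    difference_variance = sum((k_dif - dif_average)^2 * p_dif)
  )
  attr(out, "degenerate") <- degenerate
  out
}
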