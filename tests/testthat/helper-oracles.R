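# Independent brute-force oracles: scalar enumeration, no shared code with
# the package's vectorized implementations.

# discretized region built directly from an integer level array (NA = out of
# mask)
make_region <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 bin_edges = seq_len(n_levels + 1), degenerate = n_levels == 1),
            class = "DiscretizedRegion")
}

# a 1 x n strip region from a vector of levels
strip_region <- function(v, n_levels = max(v, na.rm = TRUE)) {
  make_region(array(as.integer(v), dim = c(length(v), 1, 1)), n_levels)
}

random_region <- function(dim = c(6, 6, 6), G = 4, p_mask = 0.7) {
  lv <- array(sample.int(G, prod(dim), replace = TRUE), dim = dim)
  lv[stats::runif(prod(dim)) > p_mask] <- NA_integer_
  if (!any(!is.na(lv))) lv[1] <- 1L
  make_region(lv, G)
}

# pair enumeration oracle for the co-occurrence matrix
brute_glcm <- function(region, d) {
  lv <- region$levels
  dims <- dim(lv)
  G <- region$n_levels
  C <- matrix(0, G, G)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      a <- lv[i, j, k]
      if (is.na(a)) next
      for (sgn in c(1L, -1L)) {
        ii <- i + sgn * d[1]; jj <- j + sgn * d[2]; kk <- k + sgn * d[3]
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kk < 1 || kk > dims[3]) next
        b <- lv[ii, jj, kk]
        if (is.na(b)) next
        C[a, b] <- C[a, b] + 1
      }
    }
  if (sum(C) == 0) return(C)
  C / sum(C)
}

# run enumeration oracle: walk every voxel, start a run where the
# predecessor along d is absent or different
brute_glrlm <- function(region, d) {
  lv <- region$levels
  dims <- dim(lv)
  G <- region$n_levels
  at <- function(i, j, k) {
    if (i < 1 || i > dims[1] || j < 1 || j > dims[2] ||
        k < 1 || k > dims[3]) return(NA_integer_)
    lv[i, j, k]
  }
  runs <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      g <- at(i, j, k)
      if (is.na(g)) next
      prev <- at(i - d[1], j - d[2], k - d[3])
      if (!is.na(prev) && prev == g) next
      len <- 1L
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      while (!is.na(at(ii, jj, kk)) && at(ii, jj, kk) == g) {
        len <- len + 1L
        ii <- ii + d[1]; jj <- jj + d[2]; kk <- kk + d[3]
      }
      runs[[length(runs) + 1L]] <- c(g, len)
    }
  L <- max(vapply(runs, `[`, integer(1), 2))
  R <- matrix(0L, G, L)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1L
  R
}

# direct-formula evaluation of the co-occurrence features, explicit loops
brute_glcm_features <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px)); sy <- sqrt(sum(((1:G) - muy)^2 * py))
  f <- c(autocorrelation = 0, cluster_prominence = 0, cluster_shade = 0,
         cluster_tendency = 0, contrast = 0, correlation = NaN,
         difference_entropy = 0, dissimilarity = 0, energy_asm = 0,
         entropy = 0, homogeneity1 = 0, homogeneity2 = 0, imc1 = NaN,
         imc2 = NaN, inverse_variance = 0, max_probability = 0,
         sum_average = 0, sum_entropy = 0, sum_variance = 0, variance = 0,
         difference_variance = 0)
  psum <- rep(0, 2 * G); pdif <- rep(0, G)  # indices k and k+1
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_prominence"] <- f["cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mux - muy)^3 * p
    f["cluster_tendency"] <- f["cluster_tendency"] +
      (i + j - mux - muy)^2 * p
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["energy_asm"] <- f["energy_asm"] + p^2
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["homogeneity1"] <- f["homogeneity1"] + p / (1 + abs(i - j))
    f["homogeneity2"] <- f["homogeneity2"] + p / (1 + (i - j)^2)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] +
      p / (i - j)^2
    f["max_probability"] <- max(f["max_probability"], p)
    f["variance"] <- f["variance"] + (i - mux)^2 * p
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  sa <- 0
  for (k in 2:(2 * G)) sa <- sa + k * psum[k]
  f["sum_average"] <- sa
  for (k in 2:(2 * G)) {
    if (psum[k] > 0) f["sum_entropy"] <- f["sum_entropy"] -
        psum[k] * log2(psum[k])
    f["sum_variance"] <- f["sum_variance"] + (k - sa)^2 * psum[k]
  }
  da <- 0
  for (k in 0:(G - 1)) da <- da + k * pdif[k + 1]
  for (k in 0:(G - 1)) {
    if (pdif[k + 1] > 0) f["difference_entropy"] <- f["difference_entropy"] -
        pdif[k + 1] * log2(pdif[k + 1])
    f["difference_variance"] <- f["difference_variance"] +
      (k - da)^2 * pdif[k + 1]
  }
  if (sx > 0 && sy > 0) {
    f["correlation"] <- (f[["autocorrelation"]] - mux * muy) / (sx * sy)
    hx <- 0; hy <- 0; hxy1 <- 0; hxy2 <- 0
    for (i in 1:G) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    for (j in 1:G) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
    for (i in 1:G) for (j in 1:G) {
      q <- px[i] * py[j]
      if (q > 0) {
        if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
        hxy2 <- hxy2 - q * log2(q)
      }
    }
    if (max(hx, hy) > 0) f["imc1"] <- (f[["entropy"]] - hxy1) / max(hx, hy)
    f["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f[["entropy"]]))))
  }
  f
}

# direct-formula evaluation of the run-length features
brute_glrlm_features <- function(R, n_voxels) {
  G <- nrow(R); L <- ncol(R)
  nr <- sum(R)
  f <- c(sre = 0, lre = 0, gray_level_nonuniformity = 0,
         run_length_nonuniformity = 0, rp = 0, low_gray_run_emphasis = 0,
         high_gray_run_emphasis = 0, short_run_low_gray_emphasis = 0,
         short_run_high_gray_emphasis = 0, lrlgle = 0, lrhgle = 0)
  for (g in 1:G) for (l in 1:L) {
    r <- R[g, l]
    f["sre"] <- f["sre"] + r / l^2
    f["lre"] <- f["lre"] + r * l^2
    f["low_gray_run_emphasis"] <- f["low_gray_run_emphasis"] + r / g^2
    f["high_gray_run_emphasis"] <- f["high_gray_run_emphasis"] + r * g^2
    f["short_run_low_gray_emphasis"] <-
      f["short_run_low_gray_emphasis"] + r / (g^2 * l^2)
    f["short_run_high_gray_emphasis"] <-
      f["short_run_high_gray_emphasis"] + r * g^2 / l^2
    f["lrlgle"] <- f["lrlgle"] + r * l^2 / g^2
    f["lrhgle"] <- f["lrhgle"] + r * g^2 * l^2
  }
  for (g in 1:G) f["gray_level_nonuniformity"] <-
    f["gray_level_nonuniformity"] + sum(R[g, ])^2
  for (l in 1:L) f["run_length_nonuniformity"] <-
    f["run_length_nonuniformity"] + sum(R[, l])^2
  f <- f / nr
  f["rp"] <- nr / n_voxels
  f
}

# exhaustive pair-counting AUC oracle
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

max_rel_err <- function(a, b) {
  stopifnot(identical(is.nan(unname(a)), is.nan(unname(b))))
  # mixed relative/absolute error on the features' natural O(1) scale:
  # features defined as differences of O(1) entropies (imc1, cluster
  # shade) can cancel to ~1e-7, where machine-precision summation noise
  # (~1e-16) makes a purely relative 1e-10 comparison unattainable for
  # any implementation; on values above 1 the metric stays relative
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(0)
  max(abs(a[ok] - b[ok]) / pmax(abs(a[ok]), abs(b[ok]), 1))
}

# phantom: constant-value box on zero background
box_phantom <- function(dim = c(20, 20, 20), lo = 8, hi = 12, value = 100,
                        spacing = c(1, 1, 1)) {
  a <- array(0, dim = dim)
  a[lo:hi, lo:hi, lo:hi] <- value
  volume3d(a, spacing)
}

ball_mask <- function(radius_vox, dim, spacing = c(1, 1, 1)) {
  ctr <- (dim + 1) / 2
  idx <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                     k = seq_len(dim[3]))
  d2 <- ((idx$i - ctr[1]) * spacing[1])^2 + ((idx$j - ctr[2]) * spacing[2])^2 +
    ((idx$k - ctr[3]) * spacing[3])^2
  m <- array(d2 <= radius_vox^2, dim = dim)
  lesion_mask(m, spacing)
}

# small imbalanced subtype label set matching the discovery cohort shape
brca1_labels <- function() {
  rep(c("LuminalA", "LuminalB", "HER2", "Basal"), times = c(24, 4, 3, 6))
}

# plant an exact class shift of d_eff within-class SDs: the noise is
# residualized against the class indicator so every draw carries exactly
# the designed signal-label geometry
plant_class_signal <- function(y, d_eff, seed) {
  set.seed(seed)
  e <- stats::rnorm(length(y))
  e <- stats::resid(stats::lm(e ~ y))
  e <- e / stats::sd(e)
  d_eff * y + e
}
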