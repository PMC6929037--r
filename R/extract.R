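glcm_feature_names <- c(
  "autocorrelation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_entropy",
  "dissimilarity", "energy_asm", "entropy", "homogeneity1", "homogeneity2",
  "imc1", "imc2", "inverse_variance", "max_probability", "sum_average",
  "sum_entropy", "sum_variance", "variance", "difference_variance"
)

glrlm_feature_names <- c(
  "sre", "lre", "gray_level_nonuniformity", "run_length_nonuniformity",
  "rp", "low_gray_run_emphasis", "high_gray_run_emphasis",
  "short_run_low_gray_emphasis", "short_run_high_gray_emphasis",
  "lrlgle", "lrhgle"
)

histogram_feature_names <- c(
  "voxel_count", "gray_level_count", "energy", "entropy", "minimum",
  "maximum", "mean", "median", "range", "mean_absolute_deviation",
  "root_mean_square", "standard_deviation", "skewness", "kurtosis",
  "variance", "uniformity"
)

shape_feature_names <- c(
  "volume_mm3", "volume_cm3", "surface_area_mm2", "surface_to_volume",
  "compactness1", "compactness2", "max_3d_diameter_mm",
  "spherical_disproportion", "sphericity"
)

#' Registry of the 57-feature radiomic panel
#'
#' Enumerates every feature produced by [extract_all()] with its group
#' (histogram / shape / glcm / glrlm) and units. Texture features carry
#' their group prefix in the column name (e.g. `glcm_correlation`,
#' `glrlm_sre`); the registry order is the column order of all outputs.
#'
#' @return A data.frame with columns `name`, `group`, `units`.
#' @export
feature_registry <- function() {
  units_hist <- c(
    voxel_count = "count", gray_level_count = "count",
    energy = "intensity^2", entropy = "bits", minimum = "intensity",
    maximum = "intensity", mean = "intensity", median = "intensity",
    range = "intensity", mean_absolute_deviation = "intensity",
    root_mean_square = "intensity", standard_deviation = "intensity",
    skewness = "dimensionless", kurtosis = "dimensionless",
    variance = "intensity^2", uniformity = "dimensionless"
  )
  units_shape <- c(
    volume_mm3 = "mm^3", volume_cm3 = "cm^3", surface_area_mm2 = "mm^2",
    surface_to_volume = "1/cm", compactness1 = "dimensionless",
    compactness2 = "dimensionless", max_3d_diameter_mm = "mm",
    spherical_disproportion = "dimensionless", sphericity = "dimensionless"
  )
  rbind(
    data.frame(name = histogram_feature_names, group = "histogram",
               units = unname(units_hist[histogram_feature_names])),
    data.frame(name = shape_feature_names, group = "shape",
               units = unname(units_shape[shape_feature_names])),
    data.frame(name = paste0("glcm_", glcm_feature_names), group = "glcm",
               units = "dimensionless"),
    data.frame(name = paste0("glrlm_", glrlm_feature_names), group = "glrlm",
               units = "dimensionless")
  )
}

#' The fixed 16-feature panel used for miRNA association
#'
#' The named preset of four histogram, two shape, five co-occurrence and
#' five run-length features that downstream association and signature
#' stages can run on directly (`panel = "table5"` in [reduce_features()]).
#'
#' @return Character vector of 16 registry names.
#' @export
panel_16 <- function() {
  c("energy", "skewness", "kurtosis", "median",
    "volume_cm3", "surface_to_volume",
    "glcm_correlation", "glcm_variance", "glcm_cluster_prominence",
    "glcm_cluster_tendency", "glcm_sum_average",
    "glrlm_lre", "glrlm_sre", "glrlm_rp", "glrlm_lrlgle", "glrlm_lrhgle")
}

#' Extract the full 57-feature radiomic panel from a masked volume
#'
#' Computes 16 histogram, 9 shape, 21 co-occurrence and 11 run-length
#' features of the in-mask region. Texture matrices are built on the
#' [discretize()]d region at distance-1 displacements along the 13 unique
#' lattice directions and each texture feature is the mean over directions;
#' directions yielding an empty co-occurrence matrix, or a `NaN` feature
#' (degenerate marginal), are excluded from that feature's mean. A feature
#' undefined in every direction stays `NaN`.
#'
#' @param volume a [volume3d()] (normally a subtraction image).
#' @param mask a [lesion_mask()] on the same grid.
#' @param n_bins gray levels for discretization (default 32).
#' @return Named numeric vector of length 57, ordered as
#'   [feature_registry()].
#' @export
extract_all <- function(volume, mask, n_bins = 32L) {
  hist_f <- histogram_features(volume, mask, n_bins = n_bins)
  shape_f <- shape_features(mask)
  region <- discretize(volume, mask, n_bins = n_bins)
  n_vox <- sum(mask$values)
  dirs <- lattice_directions_3d()

  glcm_acc <- matrix(NA_real_, nrow = nrow(dirs),
                     ncol = length(glcm_feature_names))
  glrlm_acc <- matrix(NA_real_, nrow = nrow(dirs),
                      ncol = length(glrlm_feature_names))
  for (k in seq_len(nrow(dirs))) {
    P <- compute_glcm(region, dirs[k, ])
    if (!attr(P, "empty")) {
      glcm_acc[k, ] <- glcm_features(P)[glcm_feature_names]
    }
    R <- compute_glrlm(region, dirs[k, ])
    if (sum(R) > 0) {
      glrlm_acc[k, ] <- glrlm_features(R, n_vox)[glrlm_feature_names]
    }
  }
  mean_no_nan <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NaN else mean(x)
  }
  glcm_f <- apply(glcm_acc, 2, mean_no_nan)
  names(glcm_f) <- paste0("glcm_", glcm_feature_names)
  glrlm_f <- apply(glrlm_acc, 2, mean_no_nan)
  names(glrlm_f) <- paste0("glrlm_", glrlm_feature_names)

  out <- c(hist_f[histogram_feature_names], shape_f[shape_feature_names],
           glcm_f, glrlm_f)
  stopifnot(identical(names(out), feature_registry()$name))
  out
}

#' Extract features for every sample of a cohort
#'
#' @param volumes named list of subtraction [volume3d()]s (names = sample
#'   IDs).
#' @param masks named list of matching [lesion_mask()]s.
#' @param n_bins gray levels for discretization.
#' @return A data.frame with `sample_id` plus the 57 feature columns.
#' @export
extract_feature_table <- function(volumes, masks, n_bins = 32L) {
  stopifnot(length(volumes) == length(masks),
            identical(names(volumes), names(masks)))
  rows <- lapply(names(volumes), function(id) {
    extract_all(volumes[[id]], masks[[id]], n_bins = n_bins)
  })
  df <- as.data.frame(do.call(rbind, rows))
  data.frame(sample_id = names(volumes), df, check.names = FALSE,
             stringsAsFactors = FALSE)
}
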