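#' Morphological (shape and size) features
#'
#' Computes 9 shape descriptors of a binary lesion mask. Volume is voxel
#' count times voxel volume; surface area is the total area of exposed voxel
#' faces (mesh-free, slightly overestimates smooth surfaces); the maximum 3D
#' diameter is the largest pairwise Euclidean distance between surface-voxel
#' centers in mm. Sphericity-family features use the mm-scale volume and
#' surface:
#' \itemize{
#'   \item `compactness1 = V / (sqrt(pi) * A^(3/2))`
#'   \item `compactness2 = 36 * pi * V^2 / A^3`
#'   \item `spherical_disproportion = A / (4 * pi * R^2)`, `R = (3V/4pi)^(1/3)`
#'   \item `sphericity = pi^(1/3) * (6V)^(2/3) / A`
#' }
#' `surface_to_volume` is reported in 1/cm as is conventional for this panel.
#'
#' @param mask a [lesion_mask()] with at least one foreground voxel.
#' @param spacing optional spacing override in mm (defaults to the mask's).
#' @return Named numeric vector of length 9.
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "LesionMask"))
  sp <- if (is.null(spacing)) mask$spacing else as.numeric(spacing)
  m <- mask$values == 1L
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  voxel_vol <- prod(sp)
  volume_mm3 <- sum(m) * voxel_vol

  # exposed faces per axis; a face perpendicular to axis a has the area of
  # the voxel cross-section in the other two axes
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  exposed <- numeric(3)
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  is_surface <- array(FALSE, dim = d)
  for (ax in 1:3) {
    s <- shifts[[ax]]
    fwd <- pad[(2 + s[1]):(d[1] + 1 + s[1]),
               (2 + s[2]):(d[2] + 1 + s[2]),
               (2 + s[3]):(d[3] + 1 + s[3])]
    bwd <- pad[(2 - s[1]):(d[1] + 1 - s[1]),
               (2 - s[2]):(d[2] + 1 - s[2]),
               (2 - s[3]):(d[3] + 1 - s[3])]
    nf <- m & !fwd
    nb <- m & !bwd
    exposed[ax] <- sum(nf) + sum(nb)
    is_surface <- is_surface | nf | nb
  }
  surface_mm2 <- sum(exposed * face_area)

  surf_idx <- which(is_surface, arr.ind = TRUE)
  coords <- sweep(surf_idx - 1, 2, sp, `*`)
  max_diam <- if (nrow(coords) == 1L) 0 else max(stats::dist(coords))

  v <- volume_mm3
  a <- surface_mm2
  r_eq <- (3 * v / (4 * pi))^(1 / 3)
  c(
    volume_mm3 = v,
    volume_cm3 = v / 1000,
    surface_area_mm2 = a,
    surface_to_volume = a / v * 10, # 1/mm -> 1/cm
    compactness1 = v / (sqrt(pi) * a^1.5),
    compactness2 = 36 * pi * v^2 / a^3,
    max_3d_diameter_mm = max_diam,
    spherical_disproportion = a / (4 * pi * r_eq^2),
    sphericity = pi^(1 / 3) * (6 * v)^(2 / 3) / a
  )
}
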