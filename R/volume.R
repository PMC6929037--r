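#' 3D scalar volume with physical grid metadata
#'
#' A `Volume3D` is a 3D numeric array together with per-axis voxel spacing
#' (mm) and a world-space origin (mm). It carries pre-contrast, post-contrast
#' or subtraction intensities. Voxel indices are 1-based `(i, j, k)` into the
#' array; the world coordinate of a voxel center is
#' `origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array of finite voxel intensities.
#' @param spacing numeric length-3 vector of strictly positive voxel spacings
#'   in mm.
#' @param origin numeric length-3 world origin in mm (default `c(0, 0, 0)`).
#' @return An object of class `Volume3D` with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume3d(array(rnorm(8^3), dim = c(8, 8, 8)), spacing = c(1, 1, 3))
#' dim(v$values)
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array, got dimensionality ",
         if (is.array(values)) length(dim(values)) else 0L)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("volume values must all be finite")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive finite values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite values")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "Volume3D")
}

#' Binary lesion mask on a volume grid
#'
#' A `LesionMask` shares the grid (dimensions, spacing, origin) of the volume
#' it segments and stores foreground as 1, background as 0.
#'
#' @param values logical or 0/1 numeric 3D array.
#' @param spacing,origin grid metadata, as in [volume3d()].
#' @return An object of class `LesionMask`.
#' @export
lesion_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array, got dimensionality ",
         if (is.array(values)) length(dim(values)) else 0L)
  }
  vals <- values
  if (is.logical(vals)) vals <- vals * 1L
  if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
    stop("mask values must be 0/1 with no missing entries")
  }
  v <- volume3d(array(as.double(vals), dim = dim(values)), spacing, origin)
  structure(list(values = array(as.integer(v$values), dim = dim(values)),
                 spacing = v$spacing, origin = v$origin),
            class = "LesionMask")
}

#' @export
print.Volume3D <- function(x, ...) {
  cat(sprintf("<Volume3D> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.LesionMask <- function(x, ...) {
  cat(sprintf("<LesionMask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$values), paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

describe_grid <- function(v) {
  sprintf("dims %s, spacing %s, origin %s",
          paste(dim(v$values), collapse = "x"),
          paste(format(v$spacing), collapse = "x"),
          paste(format(v$origin), collapse = ","))
}

#' Subtraction image: first post-contrast minus pre-contrast
#'
#' Computes the voxelwise difference `post - pre` used throughout the pipeline
#' as the enhancing-lesion image. Both inputs must live on the same grid
#' (identical dimensions; spacing and origin equal within 1e-6 mm).
#'
#' @param post,pre [volume3d()] objects on identical grids.
#' @return A `Volume3D` holding `post - pre` with the shared grid metadata.
#' @export
subtract_volumes <- function(post, pre) {
  stopifnot(inherits(post, "Volume3D"), inherits(pre, "Volume3D"))
  if (!grid_compatible(post, pre)) {
    stop("grid mismatch between post [", describe_grid(post),
         "] and pre [", describe_grid(pre), "]")
  }
  volume3d(post$values - pre$values, post$spacing, post$origin)
}
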