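#' Read a 3D volume from NRRD or NIfTI
#'
#' Dispatches on the file extension: `.nrrd` files are parsed by the
#' package's raw-encoding NRRD reader, `.nii` / `.nii.gz` through RNifti.
#' Only 3D scalar images are accepted.
#'
#' @param path path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- volume_format(path)
  if (ext == "nrrd") {
    read_nrrd(path)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (is.null(d) || length(d) != 3L) {
      stop("expected a 3D image, got dimensionality ", length(d), " in ", path)
    }
    pd <- RNifti::pixdim(img)[seq_len(3)]
    if (any(!is.finite(pd)) || any(pd <= 0)) {
      stop("non-positive voxel spacing in ", path)
    }
    xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
    origin <- if (!is.null(xf) && all(dim(xf) == c(4, 4))) xf[1:3, 4] else c(0, 0, 0)
    volume3d(array(as.double(img), dim = d), spacing = pd, origin = origin)
  }
}

#' Write a 3D volume to NRRD or NIfTI
#'
#' NRRD output uses raw little-endian encoding (the canonical on-disk dialect
#' of this package); NIfTI output goes through RNifti. Spacing and origin
#' round-trip through both formats.
#'
#' @param volume a [volume3d()] or [lesion_mask()]; masks are written as
#'   8-bit 0/1 volumes.
#' @param path output path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "LesionMask")
  if (!is_mask && !inherits(volume, "Volume3D")) {
    stop("'volume' must be a Volume3D or LesionMask")
  }
  ext <- volume_format(path)
  if (ext == "nrrd") {
    write_nrrd(volume, path, type = if (is_mask) "uint8" else "double")
  } else {
    img <- RNifti::asNifti(array(as.double(volume$values),
                                 dim = dim(volume$values)))
    RNifti::pixdim(img) <- volume$spacing
    mat <- diag(c(volume$spacing, 1))
    mat[1:3, 4] <- volume$origin
    RNifti::qform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  }
  invisible(path)
}

#' Read a mask written by [write_volume()]
#'
#' @param path volume file holding 0/1 values.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vals <- round(v$values)
  if (!all(vals %in% c(0, 1))) stop("mask file contains non-binary values: ", path)
  lesion_mask(array(as.integer(vals), dim = dim(vals)), v$spacing, v$origin)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop("unknown volume file extension (want .nrrd, .nii or .nii.gz): ", path)
}

# --- minimal NRRD (NRRD0004, raw encoding) ---------------------------------

nrrd_types <- list(
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE)
)

parse_nrrd_vectors <- function(txt) {
  m <- gregexpr("\\(([^)]*)\\)", txt)[[1]]
  parts <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(parts, function(p) {
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of NRRD header in ", path)
    if (nchar(line) == 0L) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) {
    stop("expected a 3D NRRD, got dimensionality ", dimn, " in ", path)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "[ \t]+")[[1]])
  type <- fields[["type"]]
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  if (enc != "raw") stop("unsupported NRRD encoding (only raw): ", enc)
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    spacing <- vapply(seq_along(dirs), function(i) sqrt(sum(dirs[[i]]^2)),
                      numeric(1))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[ \t]+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  }
  n <- prod(sizes)
  data <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(data) != n) stop("truncated NRRD data in ", path)
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  volume3d(array(as.double(data), dim = sizes), spacing = spacing,
           origin = origin)
}

write_nrrd <- function(volume, path, type = "double") {
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  sizes <- dim(volume$values)
  sp <- volume$spacing
  header <- c(
    "NRRD0004",
    "# generated by radiomiR",
    paste0("type: ", type),
    "dimension: 3",
    "space dimension: 3",
    paste0("sizes: ", paste(sizes, collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            volume$origin[1], volume$origin[2], volume$origin[3])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, ""), con, sep = "\n")
  vals <- as.vector(volume$values)
  if (spec$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tabular I/O -----------------------------------------------------------

#' Write/read a miRNA expression matrix as TSV
#'
#' The on-disk layout is miRNA rows by sample columns with a header row of
#' sample IDs and the miRNA IDs in the first column (`mirna_id`).
#'
#' @param expression numeric matrix, miRNAs x samples, with dimnames.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_expression <- function(expression, path) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  df <- data.frame(mirna_id = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write/read per-sample subtype labels as two-column CSV
#'
#' @param labels data.frame with columns `sample_id`, `subtype`.
#' @param path CSV path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("sample_id", "subtype") %in% names(labels)))
  utils::write.csv(labels[, c("sample_id", "subtype")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read a feature table (samples x features) as CSV
#'
#' @param features data.frame with a `sample_id` column plus numeric feature
#'   columns.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  stopifnot("sample_id" %in% names(features))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
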