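#' Per-subtype phenotype parameters for the lesion simulator
#'
#' Bundles the knobs that make synthetic lesions differ by intrinsic breast
#' cancer subtype: lesion size (ellipsoid semi-axes), contrast enhancement
#' amplitude, texture regularity (correlation length of the in-lesion random
#' field), intensity-histogram skewness, and noise level.
#'
#' @param subtype_name one of `"LuminalA"`, `"LuminalB"`, `"HER2"`,
#'   `"Basal"`.
#' @param lesion_semiaxes_mm positive length-3 mean semi-axes in mm.
#' @param semiaxes_spread_mm sd of the per-sample semi-axis draw (mm).
#' @param enhancement_amplitude positive mean post-minus-pre enhancement
#'   inside the lesion (arbitrary subtraction units).
#' @param texture_corr_length_mm positive correlation length of the
#'   in-lesion Gaussian random field (mm); larger values give smoother,
#'   longer-run texture.
#' @param histogram_skew target skewness direction/strength of the in-lesion
#'   intensity histogram (0 = symmetric).
#' @param noise_sd positive noise standard deviation (subtraction units),
#'   used both for the in-lesion texture amplitude and background noise.
#' @return A `SubtypeParams` list.
#' @export
subtype_params <- function(subtype_name, lesion_semiaxes_mm,
                           semiaxes_spread_mm = 1.5,
                           enhancement_amplitude = 120,
                           texture_corr_length_mm = 3,
                           histogram_skew = 0,
                           noise_sd = 30) {
  subtypes <- c("LuminalA", "LuminalB", "HER2", "Basal")
  if (!subtype_name %in% subtypes) {
    stop("unknown subtype: ", subtype_name)
  }
  stopifnot(length(lesion_semiaxes_mm) == 3L, all(lesion_semiaxes_mm > 0),
            semiaxes_spread_mm >= 0, enhancement_amplitude > 0,
            texture_corr_length_mm > 0, noise_sd >= 0)
  structure(list(subtype_name = subtype_name,
                 lesion_semiaxes_mm = as.numeric(lesion_semiaxes_mm),
                 semiaxes_spread_mm = semiaxes_spread_mm,
                 enhancement_amplitude = enhancement_amplitude,
                 texture_corr_length_mm = texture_corr_length_mm,
                 histogram_skew = histogram_skew,
                 noise_sd = noise_sd),
            class = "SubtypeParams")
}

#' Default subtype phenotypes
#'
#' Luminal A lesions are simulated smaller, weakly enhancing and texturally
#' regular; Luminal B, HER2+ and Basal lesions are progressively larger,
#' more strongly enhancing, more heterogeneous (shorter texture correlation
#' length) and more right-skewed, matching the qualitative ordering of
#' aggressiveness across intrinsic subtypes.
#'
#' @return Named list of four [subtype_params()].
#' @export
default_subtype_params <- function() {
  list(
    LuminalA = subtype_params("LuminalA", c(7, 6, 6), 1.2,
                              enhancement_amplitude = 120,
                              texture_corr_length_mm = 3.0,
                              histogram_skew = 0.3, noise_sd = 30),
    LuminalB = subtype_params("LuminalB", c(8, 7, 7), 1.2,
                              enhancement_amplitude = 150,
                              texture_corr_length_mm = 2.5,
                              histogram_skew = 0.5, noise_sd = 35),
    HER2 = subtype_params("HER2", c(9, 8, 7), 1.2,
                          enhancement_amplitude = 170,
                          texture_corr_length_mm = 2.0,
                          histogram_skew = 0.7, noise_sd = 40),
    Basal = subtype_params("Basal", c(10, 9, 8), 1.5,
                           enhancement_amplitude = 180,
                           texture_corr_length_mm = 1.5,
                           histogram_skew = 0.9, noise_sd = 45)
  )
}

#' Grid specification helper
#'
#' @param dim integer length-3 grid dimensions (voxels), each >= 16.
#' @param spacing positive voxel spacing in mm.
#' @param origin world origin in mm.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(dim = c(48, 48, 48), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 16L),
            length(spacing) == 3L, all(spacing > 0))
  list(dim = dim, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

# separable Gaussian smoothing, sigma in voxels per axis; kernel renormalized
# at the array edges
gauss_smooth_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    out <- matrix(0, nrow = dp[1], ncol = ncol(m))
    wsum <- numeric(dp[1])
    for (off in -half:half) {
      src <- seq_len(dp[1]) + off
      ok <- src >= 1 & src <= dp[1]
      w <- k[off + half + 1]
      out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + w
    }
    out <- out / wsum
    a <- aperm(array(out, dim = dp), order(perm))
  }
  a
}

# power transform on the min-shifted field to tilt histogram skewness,
# re-standardized to zero mean / unit sd over the in-lesion voxels
apply_skew <- function(z, skew) {
  if (skew == 0) return(z)
  u <- z - min(z) + 1e-8
  p <- if (skew > 0) 1 + skew else 1 / (1 - skew)
  y <- u^p
  (y - mean(y)) / stats::sd(y)
}

#' Simulate a pre/post-contrast volume pair with one enhancing lesion
#'
#' Draws ellipsoid semi-axes around the subtype means, places the lesion at
#' the grid center, and builds the subtraction signal as
#' `enhancement_amplitude + noise_sd * texture` inside the lesion (texture: a
#' white-noise field smoothed with an isotropic Gaussian kernel of width
#' `texture_corr_length_mm`, skew-transformed, standardized over the lesion)
#' and zero-mean noise of sd `noise_sd` outside. The pre-contrast volume is a
#' constant tissue baseline plus independent noise; `post = pre + signal`.
#'
#' @param params a [subtype_params()].
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return List with elements `pre`, `post` ([volume3d()]), `truth`
#'   ([lesion_mask()]) and `semiaxes_mm` (the drawn semi-axes).
#' @export
generate_lesion_volume <- function(params, grid = grid_spec(), seed = 1L) {
  stopifnot(inherits(params, "SubtypeParams"))
  set.seed(seed)
  dims <- grid$dim
  sp <- grid$spacing
  extent <- dims * sp

  semi <- pmax(1.5, stats::rnorm(3, params$lesion_semiaxes_mm,
                                 params$semiaxes_spread_mm))
  center <- grid$origin + extent / 2
  axis_names <- c("x", "y", "z")
  for (ax in 1:3) {
    if (center[ax] - semi[ax] < grid$origin[ax] ||
        center[ax] + semi[ax] > grid$origin[ax] + extent[ax]) {
      stop("lesion ellipsoid overflows the grid along axis ", axis_names[ax])
    }
  }

  coord <- lapply(1:3, function(ax) {
    grid$origin[ax] + (seq_len(dims[ax]) - 1) * sp[ax]
  })
  e1 <- ((coord[[1]] - center[1]) / semi[1])^2
  e2 <- ((coord[[2]] - center[2]) / semi[2])^2
  e3 <- ((coord[[3]] - center[3]) / semi[3])^2
  q <- outer(outer(e1, e2, `+`), e3, `+`)
  truth <- q <= 1
  if (!any(truth)) stop("drawn ellipsoid contains no voxel center")

  signal <- array(0, dim = dims)
  if (params$noise_sd > 0) {
    white <- array(stats::rnorm(prod(dims)), dim = dims)
    tex <- gauss_smooth_3d(white, params$texture_corr_length_mm / sp)
    tl <- tex[truth]
    if (stats::sd(tl) > 0) {
      tl <- (tl - mean(tl)) / stats::sd(tl)
      tl <- apply_skew(tl, params$histogram_skew)
    } else {
      tl <- rep(0, sum(truth))
    }
    signal[truth] <- params$noise_sd * tl
    signal[!truth] <- stats::rnorm(sum(!truth), 0, params$noise_sd)
  }
  signal[truth] <- signal[truth] + params$enhancement_amplitude

  baseline <- 100
  pre_vals <- array(baseline, dim = dims)
  if (params$noise_sd > 0) {
    pre_vals <- pre_vals + array(stats::rnorm(prod(dims), 0, params$noise_sd),
                                 dim = dims)
  }
  pre <- volume3d(pre_vals, sp, grid$origin)
  post <- volume3d(pre_vals + signal, sp, grid$origin)
  list(pre = pre, post = post,
       truth = lesion_mask(truth, sp, grid$origin),
       semiaxes_mm = semi)
}

#' Specify planted miRNA-feature correlations
#'
#' @param mirna_id character vector of miRNA names.
#' @param feature_name character vector of imaging-feature registry names.
#' @param target_r numeric vector of planted Pearson correlations, each in
#'   `(-1, 1)`.
#' @return A `LinkageSpec` data.frame.
#' @export
linkage_spec <- function(mirna_id, feature_name, target_r) {
  stopifnot(length(mirna_id) == length(feature_name),
            length(mirna_id) == length(target_r))
  if (any(abs(target_r) >= 1)) stop("|target_r| must be < 1")
  structure(data.frame(mirna_id = mirna_id, feature_name = feature_name,
                       target_r = target_r, stringsAsFactors = FALSE),
            class = c("LinkageSpec", "data.frame"))
}

#' Default planted linkage
#'
#' Mirrors the kind of miRNA/imaging-feature association the association
#' stage is meant to recover: run-length, histogram and volume features each
#' linked to one named miRNA at a planted correlation of 0.6 (a package
#' choice; see the methods vignette).
#'
#' @param target_r planted correlation strength (default 0.6).
#' @return A [linkage_spec()].
#' @export
default_linkage <- function(target_r = 0.6) {
  linkage_spec(
    mirna_id = c("miR-1537", "miR-205", "miR-335", "miR-337",
                 "miR-99a", "miR-135b", "miR-155", "miR-452"),
    feature_name = c("glrlm_rp", "median", "volume_cm3", "glrlm_sre",
                     "glrlm_lrlgle", "kurtosis", "glcm_variance", "skewness"),
    target_r = rep(target_r, 8)
  )
}

#' Default subtype mean shifts on the standardized expression scale
#'
#' miR-99a is shifted up in Luminal A (i.e. reduced in the other subtypes);
#' miR-135b and miR-155 are shifted up in the non-Luminal-A subtypes.
#' Shifts are in within-subtype SD units.
#'
#' @return Named list: miRNA -> named numeric vector of per-subtype shifts.
#' @export
default_subtype_shifts <- function() {
  up_others <- c(LuminalA = 0, LuminalB = 1, HER2 = 1, Basal = 1)
  list(
    "miR-99a" = c(LuminalA = 1, LuminalB = 0, HER2 = 0, Basal = 0),
    "miR-135b" = up_others,
    "miR-155" = up_others
  )
}

#' Simulate miRNA expression with planted imaging-feature correlations
#'
#' Each linked miRNA `m` with target correlation `r` to feature `f` is built
#' on a standardized scale as `r * standardize(f) + sqrt(1 - r^2) * noise`;
#' unlinked miRNAs are pure noise, independent of every feature. Optional
#' per-subtype mean shifts are added on this standardized (log-like) scale.
#' The reported matrix maps the standardized values affinely onto a positive
#' scale (`center + z`, default center 8, resembling log2-normalized
#' counts); an affine map preserves every planted Pearson correlation
#' exactly.
#'
#' @param labels character vector of per-sample subtypes (defines sample
#'   order and count).
#' @param features feature data.frame with `sample_id` plus feature columns,
#'   one row per label, or `NULL` when no linkage is planted.
#' @param linkage a [linkage_spec()] (may have zero rows).
#' @param n_mirnas total number of miRNAs (linked ones first, the rest
#'   independent nulls named `miR-null-XX`).
#' @param seed integer RNG seed.
#' @param subtype_shifts optional list as [default_subtype_shifts()].
#' @param sample_ids column names (default from `features$sample_id` or
#'   `sample_1..n`).
#' @param center positive offset of the reporting scale.
#' @return Numeric matrix, miRNAs x samples.
#' @export
generate_expression <- function(labels, features = NULL,
                                linkage = linkage_spec(character(), character(), numeric()),
                                n_mirnas = 20L, seed = 1L,
                                subtype_shifts = NULL,
                                sample_ids = NULL, center = 8) {
  n <- length(labels)
  if (any(abs(linkage$target_r) >= 1)) stop("|target_r| must be < 1")
  if (nrow(linkage) > 0) {
    if (is.null(features)) stop("linkage given but no feature table")
    if (nrow(features) != n) stop("features must have one row per label")
    missing_f <- setdiff(linkage$feature_name, names(features))
    if (length(missing_f) > 0) {
      stop("linked feature(s) absent from table: ",
           paste(missing_f, collapse = ", "))
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(features) && "sample_id" %in% names(features)) {
      features$sample_id
    } else {
      sprintf("sample_%03d", seq_len(n))
    }
  }
  n_mirnas <- max(as.integer(n_mirnas), nrow(linkage))
  ids <- c(linkage$mirna_id,
           sprintf("miR-null-%02d", seq_len(n_mirnas - nrow(linkage))))

  set.seed(seed)
  z <- matrix(NA_real_, nrow = n_mirnas, ncol = n,
              dimnames = list(ids, sample_ids))
  for (m in seq_len(n_mirnas)) {
    if (m <= nrow(linkage)) {
      f <- features[[linkage$feature_name[m]]]
      if (stats::sd(f) == 0) stop("linked feature is constant: ",
                                  linkage$feature_name[m])
      fs <- (f - mean(f)) / stats::sd(f)
      r <- linkage$target_r[m]
      z[m, ] <- r * fs + sqrt(1 - r^2) * stats::rnorm(n)
    } else {
      z[m, ] <- stats::rnorm(n)
    }
  }
  if (!is.null(subtype_shifts)) {
    for (id in intersect(names(subtype_shifts), ids)) {
      shift <- subtype_shifts[[id]]
      z[id, ] <- z[id, ] + unname(shift[labels])
    }
  }
  z + center
}

#' Cohort configuration presets
#'
#' `"brca1"` emulates the discovery cohort shape: paired imaging and
#' expression for 24 Luminal A, 4 Luminal B, 3 HER2+ and 6 Basal samples
#' (37 total). `"brca2"` is the imaging-only validation shape
#' (15/5/3/4 = 27). `"gse81000"` is the expression-only validation shape
#' (155/89/42/45 = 331 samples).
#'
#' @param preset one of `"brca1"`, `"brca2"`, `"gse81000"`.
#' @param n_mirnas total simulated miRNAs.
#' @param target_r planted correlation for the default linkage.
#' @return A `cohort_config` list with fields `counts`, `modality`,
#'   `subtypes`, `grid`, `linkage`, `subtype_shifts`, `n_mirnas`, `n_bins`.
#' @export
cohort_config <- function(preset = c("brca1", "brca2", "gse81000"),
                          n_mirnas = 20L, target_r = 0.6) {
  preset <- match.arg(preset)
  counts <- switch(preset,
    brca1 = c(LuminalA = 24, LuminalB = 4, HER2 = 3, Basal = 6),
    brca2 = c(LuminalA = 15, LuminalB = 5, HER2 = 3, Basal = 4),
    gse81000 = c(LuminalA = 155, LuminalB = 89, HER2 = 42, Basal = 45)
  )
  list(preset = preset,
       counts = counts,
       modality = if (preset == "gse81000") "expression" else "imaging",
       subtypes = default_subtype_params(),
       grid = grid_spec(),
       linkage = if (preset == "gse81000") {
         linkage_spec(character(), character(), numeric())
       } else {
         default_linkage(target_r)
       },
       subtype_shifts = default_subtype_shifts(),
       n_mirnas = as.integer(n_mirnas),
       n_bins = 32L)
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + i * 104729) %%
               2147483629) + 1L
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "subtypes")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_len(nchar(txt))) %% 4294967291)
}

#' Generate a full synthetic cohort
#'
#' For imaging presets, simulates a pre/post volume pair and truth mask per
#' sample (per-sample seeds derived deterministically from the master seed),
#' extracts the 57-feature panel on the truth-masked subtraction image, and
#' simulates miRNA expression with the configured planted linkage and
#' subtype shifts. Expression-only presets skip the imaging arm.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return A `SyntheticCohort` list: `samples` (per-sample list of `pre`,
#'   `post`, `truth`, `subtype`), `labels` (data.frame `sample_id`,
#'   `subtype`), `features` (truth-mask feature table, imaging presets
#'   only), `expression` (miRNAs x samples), `provenance`.
#' @export
generate_cohort <- function(config = cohort_config("brca1"), seed = 1L) {
  if (any(config$counts < 0)) stop("subtype counts must be >= 0")
  labels <- rep(names(config$counts), times = config$counts)
  n <- length(labels)
  if (n == 0) stop("empty cohort")
  sample_ids <- sprintf("%s_%03d", config$preset, seq_len(n))
  labels_df <- data.frame(sample_id = sample_ids, subtype = labels,
                          stringsAsFactors = FALSE)

  samples <- NULL
  features <- NULL
  if (config$modality == "imaging") {
    samples <- vector("list", n)
    names(samples) <- sample_ids
    feat_rows <- vector("list", n)
    for (i in seq_len(n)) {
      lesion <- generate_lesion_volume(config$subtypes[[labels[i]]],
                                       grid = config$grid,
                                       seed = derive_seed(seed, i))
      sub <- subtract_volumes(lesion$post, lesion$pre)
      feat_rows[[i]] <- extract_all(sub, lesion$truth,
                                    n_bins = config$n_bins)
      samples[[i]] <- list(sample_id = sample_ids[i], subtype = labels[i],
                           pre = lesion$pre, post = lesion$post,
                           truth = lesion$truth)
    }
    features <- data.frame(sample_id = sample_ids,
                           as.data.frame(do.call(rbind, feat_rows)),
                           check.names = FALSE, stringsAsFactors = FALSE)
  }
  expression <- generate_expression(
    labels, features = features, linkage = config$linkage,
    n_mirnas = config$n_mirnas, seed = derive_seed(seed, 0L),
    subtype_shifts = config$subtype_shifts, sample_ids = sample_ids
  )
  structure(list(samples = samples, labels = labels_df, features = features,
                 expression = expression,
                 provenance = list(seed = seed,
                                   config_hash = config_hash(config),
                                   preset = config$preset)),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("<SyntheticCohort> preset %s: %d samples (%s), %d miRNAs%s\n",
              x$provenance$preset, nrow(x$labels),
              paste(sprintf("%d %s", table(x$labels$subtype)[unique(x$labels$subtype)],
                            unique(x$labels$subtype)), collapse = ", "),
              nrow(x$expression),
              if (is.null(x$samples)) ", expression-only" else ""))
  invisible(x)
}

#' Write a cohort's artifacts to disk
#'
#' Volumes and truth masks as NRRD, expression as TSV, labels as CSV,
#' features (if present) as CSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (!is.null(cohort$samples)) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (s in cohort$samples) {
      write_volume(s$pre, file.path(vdir, paste0(s$sample_id, "_pre.nrrd")))
      write_volume(s$post, file.path(vdir, paste0(s$sample_id, "_post.nrrd")))
      write_volume(s$truth, file.path(vdir, paste0(s$sample_id, "_truth.nrrd")))
    }
    paths$volumes <- vdir
  }
  paths$expression <- write_expression(cohort$expression,
                                       file.path(dir, "expression.tsv"))
  paths$labels <- write_labels(cohort$labels, file.path(dir, "labels.csv"))
  if (!is.null(cohort$features)) {
    paths$features <- write_features(cohort$features,
                                     file.path(dir, "features_truth.csv"))
  }
  invisible(paths)
}
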