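noiseless_params <- function(amplitude = 80) {
  subtype_params("LuminalA", c(5, 5, 5), semiaxes_spread_mm = 0,
                 enhancement_amplitude = amplitude,
                 texture_corr_length_mm = 3, histogram_skew = 0,
                 noise_sd = 0)
}

test_that("noiseless lesions enhance by exactly the amplitude", {
  les <- generate_lesion_volume(noiseless_params(80), grid_spec(), seed = 1)
  sub <- subtract_volumes(les$post, les$pre)
  inside <- les$truth$values == 1L
  expect_true(all(sub$values[inside] == 80))
  expect_true(all(sub$values[!inside] == 0))
  expect_true(all(les$pre$values == 100))
})

test_that("voxelized ellipsoid volume matches the brute-force count", {
  les <- generate_lesion_volume(noiseless_params(), grid_spec(), seed = 3)
  n <- sum(les$truth$values)
  # independent brute-force voxelization of a radius-5 ball on this grid
  ctr <- 48 / 2
  idx <- expand.grid(x = 0:47, y = 0:47, z = 0:47)
  n_brute <- sum((idx$x - ctr)^2 + (idx$y - ctr)^2 + (idx$z - ctr)^2 <= 25)
  expect_equal(n, n_brute)
  expect_lt(abs(n - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
})

test_that("lesion generation is bit-identical under the same seed", {
  p <- default_subtype_params()$Basal
  a <- generate_lesion_volume(p, grid_spec(), seed = 99)
  b <- generate_lesion_volume(p, grid_spec(), seed = 99)
  expect_identical(a$post$values, b$post$values)
  expect_identical(a$pre$values, b$pre$values)
  expect_identical(a$truth$values, b$truth$values)
  c <- generate_lesion_volume(p, grid_spec(), seed = 100)
  expect_false(identical(a$post$values, c$post$values))
})

test_that("oversized ellipsoids fail naming the overflow axis", {
  p <- subtype_params("LuminalA", c(40, 5, 5), semiaxes_spread_mm = 0)
  expect_error(generate_lesion_volume(p, grid_spec(c(48, 48, 48))),
               "axis x")
  p2 <- subtype_params("LuminalA", c(5, 5, 40), semiaxes_spread_mm = 0)
  expect_error(generate_lesion_volume(p2, grid_spec(c(48, 48, 48))),
               "axis z")
})

test_that("in-lesion texture is smoother with longer correlation length", {
  mk <- function(corr) {
    p <- subtype_params("LuminalA", c(10, 10, 10), 0,
                        enhancement_amplitude = 100,
                        texture_corr_length_mm = corr, noise_sd = 20)
    les <- generate_lesion_volume(p, grid_spec(), seed = 4)
    sub <- subtract_volumes(les$post, les$pre)
    region <- discretize(sub, les$truth, 16)
    mean(vapply(1:13, function(k) {
      R <- compute_glrlm(region, lattice_directions_3d()[k, ])
      glrlm_features(R, sum(les$truth$values))[["sre"]]
    }, numeric(1)))
  }
  # longer correlation length -> longer runs -> smaller short-run emphasis
  expect_lt(mk(4), mk(1))
})

test_that("positive histogram_skew tilts the in-lesion histogram right", {
  mk <- function(skew) {
    p <- subtype_params("LuminalA", c(10, 10, 10), 0,
                        enhancement_amplitude = 100,
                        texture_corr_length_mm = 2, histogram_skew = skew,
                        noise_sd = 20)
    les <- generate_lesion_volume(p, grid_spec(), seed = 8)
    sub <- subtract_volumes(les$post, les$pre)
    histogram_features(sub, les$truth)[["skewness"]]
  }
  expect_gt(mk(1), mk(0) + 0.2)
})

test_that("planted expression correlations are recovered empirically", {
  set.seed(1)
  n <- 331
  labels <- rep("LuminalA", n)
  feats <- data.frame(sample_id = sprintf("s%03d", 1:n), f1 = rnorm(n))
  link <- linkage_spec("miR-x", "f1", 0.99)
  e <- generate_expression(labels, feats, link, n_mirnas = 10, seed = 2)
  expect_lt(abs(cor(e["miR-x", ], feats$f1) - 0.99), 0.03)
  # unlinked miRNAs: |r| at the O(1/sqrt(n)) null scale
  null_r <- vapply(grep("null", rownames(e)), function(m) {
    cor(e[m, ], feats$f1)
  }, numeric(1))
  expect_lt(max(abs(null_r)), 0.25)
  expect_lt(mean(abs(null_r)), 0.1)
  # determinism
  e2 <- generate_expression(labels, feats, link, n_mirnas = 10, seed = 2)
  expect_identical(e, e2)
  expect_error(linkage_spec("m", "f1", 1.0), "target_r")
})

test_that("subtype shifts act on the standardized scale", {
  labels <- brca1_labels()
  e <- generate_expression(labels, n_mirnas = 5, seed = 3,
                           subtype_shifts = list(
                             "miR-null-01" = c(LuminalA = 2, LuminalB = 0,
                                               HER2 = 0, Basal = 0)))
  la <- labels == "LuminalA"
  expect_gt(mean(e["miR-null-01", la]) - mean(e["miR-null-01", !la]), 1)
  expect_true(all(e > 0))
})

test_that("cohort presets reproduce the study shapes", {
  cfg <- cohort_config("gse81000")
  cohort <- generate_cohort(cfg, seed = 6)
  expect_equal(ncol(cohort$expression), 331)
  expect_equal(sum(cohort$labels$subtype == "LuminalA"), 155)
  expect_equal(sum(cohort$labels$subtype != "LuminalA"), 176)
  expect_null(cohort$samples)

  expect_equal(unname(cohort_config("brca1")$counts),
               c(24, 4, 3, 6))
  expect_equal(sum(cohort_config("brca2")$counts), 27)
})

test_that("a zero-count subtype is simply absent", {
  cfg <- cohort_config("gse81000")
  cfg$counts <- c(LuminalA = 5, LuminalB = 0, HER2 = 3, Basal = 2)
  cohort <- generate_cohort(cfg, seed = 1)
  expect_false("LuminalB" %in% cohort$labels$subtype)
  expect_equal(nrow(cohort$labels), 10)
  cfg$counts <- c(LuminalA = -1, LuminalB = 0, HER2 = 3, Basal = 2)
  expect_error(generate_cohort(cfg, seed = 1), ">= 0")
})

test_that("imaging cohorts are deterministic and internally consistent", {
  cfg <- cohort_config("brca1")
  cfg$counts <- c(LuminalA = 4, LuminalB = 0, HER2 = 0, Basal = 3)
  cfg$grid <- grid_spec(c(32, 32, 32))
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$expression, b$expression)
  expect_identical(a$features, b$features)
  expect_identical(a$samples[[1]]$post$values, b$samples[[1]]$post$values)
  expect_identical(colnames(a$expression), a$labels$sample_id)
  expect_equal(nrow(a$features), 7)
  expect_equal(a$provenance$seed, 11)
})
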