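test_that("co-occurrence matrix matches pair enumeration on a strip", {
  r <- strip_region(c(1, 1, 2, 2))
  P <- compute_glcm(r, c(1, 0, 0))
  expect_equal(unclass(P)[1:2, 1:2],
               matrix(c(1 / 3, 1 / 6, 1 / 6, 1 / 3), 2, 2),
               ignore_attr = TRUE)
  expect_false(attr(P, "empty"))
})

test_that("degenerate and symmetric co-occurrence cases", {
  rc <- strip_region(rep(1, 5), n_levels = 1)
  Pc <- compute_glcm(rc, c(1, 0, 0))
  expect_equal(Pc[1, 1], 1) # constant strip: single entry
  set.seed(21)
  r <- random_region()
  for (k in 1:3) {
    d <- lattice_directions_3d()[k, ]
    P <- compute_glcm(r, d)
    Pm <- compute_glcm(r, -d)
    expect_equal(unclass(P), unclass(Pm), ignore_attr = TRUE) # d vs -d
    expect_equal(sum(P), 1)
    expect_equal(unclass(P), t(unclass(P)), ignore_attr = TRUE)
  }
  # orthogonal displacement with no in-mask pairs -> flagged empty
  r1 <- strip_region(c(1, 2, 1))
  Pe <- compute_glcm(r1, c(0, 1, 0))
  expect_true(attr(Pe, "empty"))
})

test_that("co-occurrence features match hand values on the 2x2 matrix", {
  P <- matrix(c(1 / 3, 1 / 6, 1 / 6, 1 / 3), 2, 2)
  f <- glcm_features(P)
  expect_length(f, 21)
  expect_equal(f[["sum_average"]], 3)
  expect_equal(f[["correlation"]], 1 / 3)
  expect_equal(f[["variance"]], 0.25)
  expect_equal(f[["cluster_tendency"]], 2 / 3)
  expect_equal(f[["cluster_prominence"]], 2 / 3)
  # pigeonhole bound on the mode
  expect_gte(f[["max_probability"]], 1 / 4)
})

test_that("degenerate marginals flag correlation-family features as NaN", {
  f <- glcm_features(matrix(1, 1, 1))
  expect_true(is.nan(f[["correlation"]]))
  expect_true(is.nan(f[["imc1"]]))
  expect_true(is.nan(f[["imc2"]]))
  expect_true(attr(f, "degenerate"))
})

test_that("run-length matrix matches run enumeration on strips", {
  R <- compute_glrlm(strip_region(c(1, 1, 2, 2, 2)), c(1, 0, 0))
  expect_equal(R[1, 2], 1L) # run (level 1, length 2)
  expect_equal(R[2, 3], 1L) # run (level 2, length 3)
  expect_equal(sum(R), 2L)
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  expect_equal(sum(l * R), 5) # voxel conservation

  # all-distinct values: every run has length 1
  R2 <- compute_glrlm(strip_region(1:6), c(1, 0, 0))
  expect_equal(ncol(R2), 1L)
  expect_equal(sum(R2), 6L)

  # constant strip: one run of full length
  R3 <- compute_glrlm(strip_region(rep(1, 7), 1), c(1, 0, 0))
  expect_equal(R3[1, 7], 1L)
  expect_equal(sum(R3), 1L)
})

test_that("run-length features match hand values", {
  R <- matrix(0L, 2, 3)
  R[1, 2] <- 1L
  R[2, 3] <- 1L
  f <- glrlm_features(R, n_voxels = 5)
  expect_length(f, 11)
  expect_equal(f[["sre"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(f[["lre"]], (4 + 9) / 2)
  expect_equal(f[["rp"]], 0.4)
  # all runs length 1: SRE = LRE = RP = 1
  R1 <- matrix(c(2L, 3L), 2, 1)
  f1 <- glrlm_features(R1, n_voxels = 5)
  expect_equal(f1[["sre"]], 1)
  expect_equal(f1[["lre"]], 1)
  expect_equal(f1[["rp"]], 1)
  expect_error(glrlm_features(matrix(0L, 2, 2), 4), "zero runs")
})

test_that("texture pipeline equals brute-force enumeration on random regions", {
  set.seed(77)
  dirs <- lattice_directions_3d()
  for (rep in 1:8) {
    r <- random_region(G = sample(2:4, 1))
    n_vox <- sum(!is.na(r$levels))
    for (k in sample(nrow(dirs), 4)) {
      d <- dirs[k, ]
      P <- compute_glcm(r, d)
      Pb <- brute_glcm(r, d)
      expect_lt(max(abs(unclass(P) - Pb)), 1e-12)
      if (!attr(P, "empty")) {
        expect_lt(max_rel_err(glcm_features(P), brute_glcm_features(Pb)),
                  1e-10)
      }
      R <- compute_glrlm(r, d)
      Rb <- brute_glrlm(r, d)
      expect_equal(unclass(R)[, seq_len(ncol(Rb)), drop = FALSE], Rb,
                   ignore_attr = TRUE)
      expect_lt(max_rel_err(glrlm_features(R, n_vox),
                            brute_glrlm_features(Rb, n_vox)), 1e-10)
    }
  }
})

test_that("run-length conservation holds along every direction", {
  set.seed(42)
  r <- random_region(dim = c(7, 6, 5), G = 3)
  n_vox <- sum(!is.na(r$levels))
  for (k in seq_len(13)) {
    R <- compute_glrlm(r, lattice_directions_3d()[k, ])
    l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
    expect_equal(sum(l * R), n_vox)
  }
})
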