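test_that("rank correlation behaves as Pearson on ranks", {
  x <- c(1, 2, 3, 4)
  tab <- data.frame(sample_id = letters[1:4], a = x, b = exp(x),
                    c = c(1, 3, 2, 4))
  rho <- spearman_matrix(tab)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho["a", "b"], 1)       # strictly increasing transform
  expect_equal(rho["a", "c"], 0.8)     # Pearson of ranks
  expect_equal(rho, t(rho))
  expect_error(spearman_matrix(tab[1:2, ]), ">= 3")
})

test_that("constant features yield NA correlations, treated as no edge", {
  tab <- data.frame(sample_id = letters[1:5], a = rnorm(5), k = rep(2, 5))
  rho <- spearman_matrix(tab)
  expect_true(is.na(rho["a", "k"]))
  cl <- cluster_redundant(rho, 0.5)
  expect_length(cl, 2) # the constant feature stays a singleton
})

test_that("clustering is connected components of the |rho| graph", {
  rho <- diag(3)
  dimnames(rho) <- list(c("A", "B", "C"), c("A", "B", "C"))
  # chain: A-B and B-C strong, A-C weak -> one cluster through B
  rho["A", "B"] <- rho["B", "A"] <- 0.9
  rho["B", "C"] <- rho["C", "B"] <- 0.9
  rho["A", "C"] <- rho["C", "A"] <- 0.2
  cl <- cluster_redundant(rho, 0.8)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], c("A", "B", "C"))
  # no edges: all singletons
  cl2 <- cluster_redundant(rho, 0.95)
  expect_length(cl2, 3)
  # negative correlations cluster by |rho|
  rho["A", "B"] <- rho["B", "A"] <- -0.9
  expect_length(cluster_redundant(rho, 0.8), 1)
})

test_that("duplicated features always cluster together", {
  set.seed(4)
  x <- rnorm(20)
  tab <- data.frame(sample_id = sprintf("s%02d", 1:20), a = x, dup = x,
                    z = rnorm(20))
  rho <- spearman_matrix(tab)
  for (thr in c(0.3, 0.8, 1.0)) {
    cl <- cluster_redundant(rho, thr)
    grp <- vapply(cl, function(g) all(c("a", "dup") %in% g), logical(1))
    expect_true(any(grp))
  }
})

test_that("representatives maximize the coefficient of variation", {
  set.seed(8)
  n <- 40
  base <- rnorm(n)
  tab <- data.frame(sample_id = seq_len(n),
                    A = 10 + 5 * base,   # CV = 0.5
                    B = 10 + 1 * base,   # CV = 0.1
                    lone = rnorm(n))
  rho <- spearman_matrix(tab)
  cl <- cluster_redundant(rho, 0.8)
  reps <- select_representatives(cl, tab)
  big <- which(vapply(cl, function(g) "A" %in% g, logical(1)))
  expect_equal(unname(reps[big]), "A")
  # singleton cluster represents itself
  lone_cl <- which(vapply(cl, function(g) identical(g, "lone"), logical(1)))
  expect_equal(unname(reps[lone_cl]), "lone")
})

test_that("CV ties break to the earlier column; zero-mean members skipped", {
  x <- c(-2, -1, 0, 1, 2, 3)
  tab <- data.frame(sample_id = 1:6, first = x, second = x)
  reps <- select_representatives(list(c("first", "second")), tab)
  expect_equal(unname(reps), "first")
  # zero-mean feature has CV = Inf; a finite-CV sibling wins
  tab2 <- data.frame(sample_id = 1:6, zm = x - mean(x), ok = 10 + x)
  reps2 <- select_representatives(list(c("zm", "ok")), tab2)
  expect_equal(unname(reps2), "ok")
})

test_that("raising the threshold never shrinks the panel", {
  set.seed(13)
  n <- 30
  latent <- matrix(rnorm(n * 5), n, 5)
  feats <- latent[, rep(1:5, each = 4)] + matrix(rnorm(n * 20, 0, 0.4), n, 20)
  tab <- data.frame(sample_id = seq_len(n), feats)
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.99), function(thr) {
    length(reduce_features(tab, thr)$representatives)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_lte(max(sizes), 20)
})

test_that("the fixed 16-feature panel preset bypasses reduction", {
  cols <- c("sample_id", feature_registry()$name)
  tab <- as.data.frame(matrix(rnorm(5 * 57), 5, 57))
  names(tab) <- feature_registry()$name
  tab <- cbind(sample_id = letters[1:5], tab)
  red <- reduce_features(tab, panel = "table5")
  expect_setequal(red$representatives, panel_16())
  expect_equal(ncol(red$reduced), 17)
})
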