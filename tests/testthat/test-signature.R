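test_that("subtype labels map to a Luminal A positive class", {
  expect_identical(binary_labels(c("LuminalA", "Basal", "HER2")),
                   c(1L, 0L, 0L))
  expect_identical(binary_labels(rep("LuminalA", 3)), rep(1L, 3))
  expect_error(binary_labels(c("LuminalA", "luminal-a")), "unknown subtype")
  y <- binary_labels(brca1_labels())
  expect_equal(sum(y == 1L), 24)
  expect_equal(sum(y == 0L), 13)
})

test_that("AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(1:8, n, replace = TRUE) # discrete: ties guaranteed
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  expect_error(roc_auc(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  s <- rnorm(30)
  y <- rbinom(30, 1, 0.5)
  y[1:2] <- c(0, 1)
  expect_equal(roc_auc(exp(s), y), roc_auc(s, y))
  expect_equal(roc_auc(3 * s - 7, y), roc_auc(s, y))
})

test_that("Monte Carlo splits honor the floor(0.6 n) contract", {
  y <- c(rep(1, 60), rep(0, 40))
  sp <- mc_cv_split(100, 0.6, stratified = TRUE, labels = y, seed = 5)
  expect_length(sp$train, 60)
  expect_length(sp$test, 40)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  # stratification: floor per class, remainder to the larger class
  expect_equal(sum(y[sp$train] == 1), 36)
  expect_equal(sum(y[sp$train] == 0), 24)

  y37 <- binary_labels(brca1_labels())
  sp37 <- mc_cv_split(37, 0.6, stratified = TRUE, labels = y37, seed = 1)
  expect_length(sp37$train, 22) # floor(22.2)
  expect_length(sp37$test, 15)
  expect_equal(sum(y37[sp37$train] == 1), 15) # floor(14.4) + remainder
  expect_equal(sum(y37[sp37$train] == 0), 7)  # floor(7.8)

  sp_b <- mc_cv_split(37, 0.6, stratified = TRUE, labels = y37, seed = 1)
  expect_identical(sp37, sp_b) # seed-reproducible
  sp_c <- mc_cv_split(37, 0.6, stratified = TRUE, labels = y37, seed = 2)
  expect_false(identical(sp37$train, sp_c$train))
})

test_that("the grid search evaluates exactly 12 parameter pairs", {
  set.seed(41)
  x <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  y[1:4] <- c(0, 0, 1, 1)
  fit <- train_svm_grid(x, y, cv_config(seed = 3))
  expect_equal(nrow(fit$grid), 12)
  expect_setequal(unique(fit$grid$cost), c(0.1, 1, 10, 100))
  expect_setequal(unique(fit$grid$gamma), c(0.5, 1, 2))
  expect_true(fit$cost %in% c(0.1, 1, 10, 100))
  expect_error(train_svm_grid(x, rep(1, 30)), "each class")
})

test_that("a separable training set is fit to training AUC 1", {
  set.seed(43)
  x <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c(0, 1), each = 20)
  fit <- train_svm_grid(x, y, cv_config(seed = 7))
  s <- radiomiR:::svm_score(fit$model, x)
  expect_equal(roc_auc(s, y), 1.0)
})

test_that("evaluate_signature reproduces its protocol exactly at one repeat", {
  set.seed(51)
  dat <- data.frame(f = rnorm(37) + binary_labels(brca1_labels()))
  labels <- brca1_labels()
  cfg <- cv_config(n_repeats = 1L, seed = 23)
  res <- evaluate_signature("f", dat, labels, cfg)
  # manual replay: same derived seed, split, train-only standardization
  y <- binary_labels(labels)
  seed1 <- radiomiR:::derive_seed(23L, 1L)
  sp <- mc_cv_split(37, 0.6, TRUE, y, seed = seed1)
  x <- as.matrix(dat)
  mu <- mean(x[sp$train, ])
  sdev <- sd(x[sp$train, ])
  xs <- (x - mu) / sdev
  fit <- train_svm_grid(xs[sp$train, , drop = FALSE], y[sp$train], cfg)
  s <- radiomiR:::svm_score(fit$model, xs[sp$test, , drop = FALSE])
  expect_equal(res$aucs, roc_auc(s, y[sp$test]))
  expect_equal(res$mean_auc, res$aucs[1])
})

test_that("pure-noise signatures stay near chance at n = 37", {
  set.seed(53)
  dat <- data.frame(noise = rnorm(37))
  res <- evaluate_signature("noise", dat, brca1_labels(),
                            cv_config(n_repeats = 40, seed = 3))
  expect_gte(res$mean_auc, 0.35)
  expect_lte(res$mean_auc, 0.65)
})

test_that("a strong class shift yields near-perfect cross-validated AUC", {
  # 3 pooled-SD separation; average over data draws since a single n = 37
  # draw can happen to overlap
  y <- binary_labels(brca1_labels())
  aucs <- vapply(1:3, function(d) {
    set.seed(56 + d)
    dat <- data.frame(strong = rnorm(37, 0, 1) + 3 * y)
    evaluate_signature("strong", dat, brca1_labels(),
                       cv_config(n_repeats = 40, seed = d))$mean_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.95)
})

test_that("rows with missing signature values are dropped with a warning", {
  set.seed(59)
  dat <- data.frame(f = c(NA, rnorm(36)))
  expect_warning(
    res <- evaluate_signature("f", dat, brca1_labels(),
                              cv_config(n_repeats = 2, seed = 1)),
    "dropped")
  expect_equal(res$n, 36)
})

test_that("signature enumeration has the documented combinatorics and order", {
  set.seed(61)
  n <- 37
  labels <- brca1_labels()
  y <- binary_labels(labels)
  dat <- data.frame(m1 = rnorm(n) + y, m2 = rnorm(n), m3 = rnorm(n),
                    if1 = rnorm(n) + y, if2 = rnorm(n))
  cfg <- cv_config(n_repeats = 3, seed = 2)
  rk <- enumerate_signatures(c("m1", "m2", "m3"), c("if1", "if2"),
                             dat, labels, cfg, max_size = 2)
  expect_equal(nrow(rk), 3 + 2 + 6) # singles from each pool + mirna x if pairs
  expect_equal(sum(rk$size == 1), 5)
  expect_equal(sum(rk$size == 2), 6)
  expect_true(all(diff(rk$mean_auc) <= 0))
  # triples include at least one miRNA
  rk3 <- enumerate_signatures(c("m1", "m2"), c("if1", "if2"), dat, labels,
                              cfg, max_size = 3)
  trips <- strsplit(rk3$signature[rk3$size == 3], "\\+")
  expect_equal(length(trips), choose(4, 3)) # all-IF triple impossible here
  expect_true(all(vapply(trips, function(s) any(s %in% c("m1", "m2")),
                         logical(1))))
  expect_warning(out <- enumerate_signatures(character(), character(),
                                             dat, labels, cfg),
                 "empty")
  expect_equal(nrow(out), 0)
})
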