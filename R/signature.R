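#' Binary Luminal A vs other-subtype target
#'
#' Luminal A (the low-risk class) is the positive class; Luminal B, HER2+
#' and Basal are grouped as the negative class.
#'
#' @param labels character vector of subtypes.
#' @return Integer vector of 1 (Luminal A) / 0 (other).
#' @export
binary_labels <- function(labels) {
  known <- c("LuminalA", "LuminalB", "HER2", "Basal")
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0) stop("unknown subtype label(s): ",
                            paste(bad, collapse = ", "))
  as.integer(labels == "LuminalA")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC` equals the probability that a random positive outscores a random
#' negative, ties counted one half; computed from average ranks, which is
#' exactly the normalized Mann-Whitney U statistic.
#'
#' @param scores finite numeric decision scores (higher = more positive).
#' @param labels 0/1 vector, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Monte Carlo cross-validation configuration
#'
#' Defaults follow the evaluation protocol: 60/40 train/test Monte Carlo
#' splits, radial-kernel SVM with an exhaustive grid over
#' `cost = c(0.1, 1, 10, 100)` and `gamma = c(0.5, 1, 2)` (12 parameter
#' pairs), model selection by stratified 5-fold inner cross-validated AUC
#' on the training set, 100 repeats, stratified splitting.
#'
#' @param train_fraction training fraction in `(0, 1)`.
#' @param n_repeats Monte Carlo repeats.
#' @param cost_grid,gamma_grid SVM hyperparameter grids.
#' @param stratified stratify splits by class.
#' @param inner_folds inner CV folds for the grid search.
#' @param seed master seed for the repeat stream.
#' @return A `CVConfig` list.
#' @export
cv_config <- function(train_fraction = 0.6, n_repeats = 100L,
                      cost_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(0.5, 1, 2),
                      stratified = TRUE, inner_folds = 5L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(cost_grid) > 0, length(gamma_grid) > 0)
  list(train_fraction = train_fraction, n_repeats = as.integer(n_repeats),
       cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
       kernel = "radial", stratified = isTRUE(stratified),
       inner_folds = as.integer(inner_folds), seed = as.integer(seed))
}

#' One Monte Carlo train/test split
#'
#' Training size is `floor(train_fraction * n)`; under stratification each
#' class contributes `floor(train_fraction * n_class)` and any remainder is
#' assigned to the larger class. Unstratified splits leaving a single-class
#' training set are resampled (up to 100 tries) before erroring.
#'
#' @param n number of samples (>= 5).
#' @param train_fraction fraction in `(0, 1)`.
#' @param stratified stratify by `labels`.
#' @param labels 0/1 class labels (required if stratified or for the
#'   single-class guard).
#' @param seed integer seed; identical seeds give identical splits.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering `1..n`).
#' @export
mc_cv_split <- function(n, train_fraction = 0.6, stratified = TRUE,
                        labels = NULL, seed = 1L) {
  stopifnot(n >= 5)
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("degenerate split size")
  set.seed(seed)
  if (stratified) {
    if (is.null(labels)) stop("stratified split needs labels")
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2) stop("both classes needed to stratify")
    cls <- sort(unique(labels))
    sizes <- vapply(cls, function(c) sum(labels == c), integer(1))
    take <- floor(train_fraction * sizes)
    rem <- n_train - sum(take)
    if (rem > 0) {
      ord <- order(sizes, decreasing = TRUE)
      for (k in seq_len(rem)) {
        i <- ord[(k - 1) %% length(ord) + 1]
        take[i] <- min(take[i] + 1L, sizes[i])
      }
    }
    train <- integer(0)
    for (i in seq_along(cls)) {
      idx <- which(labels == cls[i])
      train <- c(train, sample(idx, take[i]))
    }
  } else {
    for (try in seq_len(100L)) {
      train <- sample(n, n_train)
      if (is.null(labels) || length(unique(labels[train])) > 1) break
      if (try == 100L) stop("could not draw a two-class training set")
    }
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

svm_score <- function(model, x, positive = "pos") {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cn <- colnames(dv)[1]
  s <- as.numeric(dv[, 1])
  if (!startsWith(cn, paste0(positive, "/"))) s <- -s
  s
}

#' Grid-search a radial-kernel SVM on a training set
#'
#' Exhaustively evaluates every (cost, gamma) pair of the grid by
#' stratified inner k-fold cross-validated AUC on the (already
#' standardized) training data and refits the winning model on the full
#' training set. Ties break toward smaller cost, then smaller gamma. Inner
#' folds lacking a class on either side are skipped.
#'
#' @param x_train numeric matrix (samples x features), standardized.
#' @param y_train 0/1 labels, both classes with >= 2 samples.
#' @param config a [cv_config()].
#' @return List: `model` (e1071 fit), `cost`, `gamma`, `inner_auc`, `grid`
#'   (the 12-row search record).
#' @export
train_svm_grid <- function(x_train, y_train, config = cv_config()) {
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2 || min(table(y_train)) < 2) {
    stop("training set needs >= 2 samples of each class")
  }
  x_train <- as.matrix(x_train)
  yf <- factor(ifelse(y_train == 1L, "pos", "neg"), levels = c("neg", "pos"))
  k <- min(config$inner_folds, min(table(y_train)))
  fold <- integer(length(y_train))
  for (c in c(0L, 1L)) {
    idx <- which(y_train == c)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid)
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  grid$inner_auc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- fold == f
      if (length(unique(y_train[tr])) < 2 ||
          length(unique(y_train[te])) < 2) next
      fit <- e1071::svm(x_train[tr, , drop = FALSE], yf[tr],
                        kernel = "radial", cost = grid$cost[gi],
                        gamma = grid$gamma[gi], scale = FALSE)
      s <- svm_score(fit, x_train[te, , drop = FALSE])
      aucs <- c(aucs, roc_auc(s, y_train[te]))
    }
    grid$inner_auc[gi] <- if (length(aucs) > 0) mean(aucs) else NA_real_
  }
  ok <- which(!is.na(grid$inner_auc))
  best <- if (length(ok) == 0) 1L else ok[which.max(grid$inner_auc[ok])]
  model <- e1071::svm(x_train, yf, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  list(model = model, cost = grid$cost[best], gamma = grid$gamma[best],
       inner_auc = grid$inner_auc[best], grid = grid)
}

#' Evaluate one signature by Monte Carlo cross-validated AUC
#'
#' For each repeat: draw a 60/40 split, z-score each signature column using
#' training-set statistics only, grid-train the SVM on the training rows,
#' score the held-out rows, and record the test AUC. Rows with missing
#' values in the signature columns are dropped with a warning before
#' splitting.
#'
#' @param sig character vector of 1-3 column names (miRNAs and/or imaging
#'   features).
#' @param data data.frame holding those columns (one row per sample).
#' @param labels subtype labels (converted by [binary_labels()]) or
#'   already-binary 0/1 vector.
#' @param config a [cv_config()].
#' @return A `CVResult` list: `signature`, `aucs` (per repeat),
#'   `mean_auc`, `sd_auc`, `params` (chosen cost/gamma per repeat), `n`.
#' @export
evaluate_signature <- function(sig, data, labels, config = cv_config()) {
  stopifnot(length(sig) >= 1, length(sig) <= 3, !anyDuplicated(sig))
  missing_cols <- setdiff(sig, names(data))
  if (length(missing_cols) > 0) {
    stop("signature column(s) absent: ", paste(missing_cols, collapse = ", "))
  }
  y <- if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    as.integer(labels)
  } else {
    binary_labels(labels)
  }
  x <- as.matrix(data[, sig, drop = FALSE])
  keep <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with missing signature values dropped")
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(x)
  aucs <- numeric(config$n_repeats)
  params <- data.frame(cost = numeric(config$n_repeats),
                       gamma = numeric(config$n_repeats))
  for (t in seq_len(config$n_repeats)) {
    seed_t <- derive_seed(config$seed, t)
    split <- mc_cv_split(n, config$train_fraction, config$stratified, y,
                         seed = seed_t)
    mu <- colMeans(x[split$train, , drop = FALSE])
    sdev <- apply(x[split$train, , drop = FALSE], 2, stats::sd)
    sdev[sdev == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdev, `/`)
    fit <- train_svm_grid(xs[split$train, , drop = FALSE], y[split$train],
                          config)
    s <- svm_score(fit$model, xs[split$test, , drop = FALSE])
    aucs[t] <- roc_auc(s, y[split$test])
    params$cost[t] <- fit$cost
    params$gamma[t] <- fit$gamma
  }
  structure(list(signature = sig, aucs = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs), params = params, n = n),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %s: mean AUC %.3f (sd %.3f, %d repeats, n = %d)\n",
              paste(x$signature, collapse = " + "), x$mean_auc, x$sd_auc,
              length(x$aucs), x$n))
  invisible(x)
}

#' Enumerate and rank single, pair and triple signatures
#'
#' Evaluates every single from each pool, every miRNA x imaging-feature
#' pair, and (up to `max_size = 3`) every triple drawn from the union of
#' pools containing at least one miRNA. Results are sorted by mean AUC
#' descending with a deterministic tie-break on the signature name.
#'
#' @param mirna_pool,if_pool character vectors of column names (typically
#'   the association-retained miRNAs and features).
#' @param data data.frame with all pooled columns.
#' @param labels subtype (or 0/1) labels.
#' @param config a [cv_config()].
#' @param max_size 1, 2 or 3.
#' @return data.frame ranked by `mean_auc`: `signature`, `size`,
#'   `mean_auc`, `sd_auc`, `n_repeats`, plus attribute `results` (the
#'   full `CVResult` list, in ranked order).
#' @export
enumerate_signatures <- function(mirna_pool, if_pool, data, labels,
                                 config = cv_config(), max_size = 3L) {
  if (length(mirna_pool) == 0 && length(if_pool) == 0) {
    warning("empty signature pools")
    return(data.frame(signature = character(), size = integer(),
                      mean_auc = numeric(), sd_auc = numeric(),
                      n_repeats = integer()))
  }
  sigs <- lapply(c(mirna_pool, if_pool), function(s) s)
  if (max_size >= 2 && length(mirna_pool) > 0 && length(if_pool) > 0) {
    for (m in mirna_pool) for (f in if_pool) {
      sigs[[length(sigs) + 1L]] <- c(m, f)
    }
  }
  if (max_size >= 3) {
    pool <- c(mirna_pool, if_pool)
    if (length(pool) >= 3) {
      combos <- utils::combn(pool, 3, simplify = FALSE)
      combos <- Filter(function(s) any(s %in% mirna_pool), combos)
      sigs <- c(sigs, combos)
    }
  }
  results <- lapply(sigs, function(s) {
    evaluate_signature(s, data, labels, config)
  })
  tab <- data.frame(
    signature = vapply(results, function(r) paste(r$signature, collapse = "+"),
                       character(1)),
    size = vapply(results, function(r) length(r$signature), integer(1)),
    mean_auc = vapply(results, function(r) r$mean_auc, numeric(1)),
    sd_auc = vapply(results, function(r) r$sd_auc, numeric(1)),
    n_repeats = vapply(results, function(r) length(r$aucs), integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$mean_auc, tab$signature)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}
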