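#' Spearman correlation matrix of a feature table
#'
#' Rank correlation (average ranks for ties) over pairwise-complete
#' observations. A feature constant across samples has no defined rank
#' correlation; its off-diagonal entries are `NA`.
#'
#' @param features data.frame with `sample_id` plus numeric feature columns
#'   (or a plain numeric matrix/data.frame of features).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
spearman_matrix <- function(features) {
  x <- drop_sample_id(features)
  if (nrow(x) < 3) stop("need >= 3 samples for rank correlation")
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  diag(rho) <- 1
  rho
}

drop_sample_id <- function(features) {
  df <- as.data.frame(features)
  if ("sample_id" %in% names(df)) df$sample_id <- NULL
  as.matrix(df)
}

#' Cluster redundant features by correlation-graph connected components
#'
#' Builds a graph on the features with an edge wherever
#' `|rho| >= threshold` (`NA` correlations contribute no edge) and returns
#' its connected components. This is the simplest clustering rule consistent
#' with collapsing "clusters of highly correlated features".
#'
#' @param rho symmetric correlation matrix from [spearman_matrix()].
#' @param threshold absolute-correlation edge threshold in `(0, 1)`.
#' @return Named list of character vectors (feature names per cluster), in
#'   order of each cluster's first member.
#' @export
cluster_redundant <- function(rho, threshold = 0.8) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  adj <- !is.na(rho) & abs(rho) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  nm <- colnames(rho)
  split(nm, comp$membership)
}

#' Pick one representative feature per cluster by coefficient of variation
#'
#' The representative is the member with the largest coefficient of
#' variation `CV = sd / |mean|` across samples. Members with zero mean are
#' CV-unstable (`CV = Inf`) and are skipped unless every member of the
#' cluster is; all-`NA` members are excluded from candidacy. Ties resolve to
#' the member earliest in the table's column order.
#'
#' @param clusters list from [cluster_redundant()].
#' @param features the feature table the clusters were computed on.
#' @return Character vector of representative names, one per cluster.
#' @export
select_representatives <- function(clusters, features) {
  x <- drop_sample_id(features)
  order_ref <- colnames(x)
  vapply(clusters, function(members) {
    members <- members[order(match(members, order_ref))]
    cv <- vapply(members, function(m) {
      v <- x[, m]
      v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      mu <- mean(v)
      if (mu == 0) return(Inf)
      stats::sd(v) / abs(mu)
    }, numeric(1))
    ok <- !is.na(cv)
    if (!any(ok)) return(members[1])
    finite_ok <- ok & is.finite(cv)
    pool <- if (any(finite_ok)) finite_ok else ok
    cand <- members[pool]
    cand[which.max(cv[pool])]
  }, character(1))
}

#' Reduce a feature table to a non-redundant panel
#'
#' Runs [spearman_matrix()], [cluster_redundant()] and
#' [select_representatives()] and returns the reduced table plus a full
#' report. With `panel = "table5"` the fixed 16-feature association panel
#' ([panel_16()]) is used instead of data-driven reduction.
#'
#' @param features feature table (`sample_id` + feature columns).
#' @param threshold absolute Spearman threshold (default 0.8).
#' @param panel `"auto"` (default) or `"table5"`.
#' @return List of class `RedundancyReport`: `representatives`, `clusters`,
#'   `spearman`, `threshold`, `panel`, `reduced` (the reduced data.frame),
#'   `cv_flags` (zero-mean members).
#' @export
reduce_features <- function(features, threshold = 0.8,
                            panel = c("auto", "table5")) {
  panel <- match.arg(panel)
  x <- drop_sample_id(features)
  if (panel == "table5") {
    reps <- intersect(panel_16(), colnames(x))
    missing <- setdiff(panel_16(), colnames(x))
    if (length(missing) > 0) {
      warning("panel features absent from table: ",
              paste(missing, collapse = ", "))
    }
    reduced <- features[, c(intersect("sample_id", names(features)), reps),
                        drop = FALSE]
    return(structure(list(representatives = reps, clusters = as.list(reps),
                          spearman = NULL, threshold = NA_real_,
                          panel = "table5", reduced = reduced,
                          cv_flags = character()),
                     class = "RedundancyReport"))
  }
  rho <- spearman_matrix(features)
  clusters <- cluster_redundant(rho, threshold)
  reps <- select_representatives(clusters, features)
  means <- colMeans(x, na.rm = TRUE)
  cv_flags <- colnames(x)[!is.na(means) & means == 0]
  reduced <- features[, c(intersect("sample_id", names(features)),
                          unname(reps)), drop = FALSE]
  structure(list(representatives = unname(reps), clusters = clusters,
                 spearman = rho, threshold = threshold, panel = "auto",
                 reduced = reduced, cv_flags = cv_flags),
            class = "RedundancyReport")
}

#' @export
print.RedundancyReport <- function(x, ...) {
  cat(sprintf("<RedundancyReport> %d features -> %d representatives (%s)\n",
              if (is.null(x$spearman)) length(x$representatives)
              else ncol(x$spearman),
              length(x$representatives),
              if (x$panel == "table5") "fixed 16-feature panel"
              else sprintf("|rho| >= %.2f", x$threshold)))
  invisible(x)
}
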