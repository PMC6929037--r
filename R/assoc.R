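#' Pearson correlation map between imaging features and miRNA expression
#'
#' For each (feature, miRNA) pair, computes the sample Pearson correlation
#' over pairwise-complete matched samples and a two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (`|r| = 1` is reported with `p = 0`). Samples are matched by
#' `sample_id` between the feature table and the expression columns. Pairs
#' with fewer than 3 complete observations or a constant vector are
#' reported as undefined with a reason code. A Benjamini-Hochberg `q_bh`
#' column is attached for information only; retention (see
#' [filter_significant()]) uses the raw p-values.
#'
#' When `stratify` labels are supplied the map is computed within each
#' subtype stratum separately and the strata are stacked with a `stratum`
#' column (the convention used for per-subtype association heatmaps);
#' otherwise a single pooled map is returned with `stratum = "pooled"`.
#'
#' @param features data.frame with `sample_id` plus feature columns.
#' @param expression miRNAs x samples matrix with sample IDs as column
#'   names.
#' @param stratify optional data.frame (`sample_id`, `subtype`) to compute
#'   within-subtype maps.
#' @return A data.frame of class `CorrelationMap` with columns `stratum`,
#'   `feature`, `mirna`, `r`, `p`, `n`, `q_bh`, `reason` (`NA` when
#'   defined).
#' @export
pearson_map <- function(features, expression, stratify = NULL) {
  stopifnot("sample_id" %in% names(features), is.matrix(expression))
  shared <- intersect(features$sample_id, colnames(expression))
  if (length(shared) < 3) stop("need >= 3 samples shared between tables")
  strata <- if (is.null(stratify)) {
    list(pooled = shared)
  } else {
    stopifnot(all(c("sample_id", "subtype") %in% names(stratify)))
    ids <- stratify$sample_id[stratify$sample_id %in% shared]
    split(ids, stratify$subtype[stratify$sample_id %in% shared])
  }
  feat_names <- setdiff(names(features), "sample_id")
  out <- list()
  for (st in names(strata)) {
    ids <- strata[[st]]
    fx <- features[match(ids, features$sample_id), , drop = FALSE]
    ex <- expression[, ids, drop = FALSE]
    for (f in feat_names) {
      xv <- fx[[f]]
      for (m in rownames(expression)) {
        yv <- ex[m, ]
        ok <- is.finite(xv) & is.finite(yv)
        n <- sum(ok)
        r <- NA_real_
        p <- NA_real_
        reason <- NA_character_
        if (n < 3) {
          reason <- "n_too_small"
        } else if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
          reason <- "constant_vector"
        } else {
          r <- stats::cor(xv[ok], yv[ok])
          if (abs(r) >= 1) {
            r <- sign(r)
            p <- 0
          } else {
            tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
            p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, feature = f, mirna = m, r = r, p = p, n = n,
          reason = reason, stringsAsFactors = FALSE
        )
      }
    }
  }
  map <- do.call(rbind, out)
  map$q_bh <- NA_real_
  for (st in unique(map$stratum)) {
    sel <- map$stratum == st & !is.na(map$p)
    map$q_bh[sel] <- stats::p.adjust(map$p[sel], method = "BH")
  }
  class(map) <- c("CorrelationMap", "data.frame")
  map
}

#' Retain significantly correlated (feature, miRNA) pairs
#'
#' Strict `p < alpha` retention. Pairs in the borderline band
#' `alpha <= p < borderline_alpha` are reported separately but not
#' retained.
#'
#' @param map a [pearson_map()] result.
#' @param alpha significance level in `(0, 1)` (default 0.05).
#' @param borderline_alpha upper edge of the reported borderline band
#'   (default 0.10).
#' @return List with data.frames `retained` and `borderline`.
#' @export
filter_significant <- function(map, alpha = 0.05, borderline_alpha = 0.10) {
  stopifnot(alpha > 0, alpha <= 1)
  defined <- !is.na(map$p)
  retained <- map[defined & map$p < alpha, , drop = FALSE]
  borderline <- map[defined & map$p >= alpha & map$p < borderline_alpha, ,
                    drop = FALSE]
  list(retained = retained, borderline = borderline, alpha = alpha,
       borderline_alpha = borderline_alpha)
}

#' Rectangular p-value (or r) matrix for heatmap export
#'
#' @param map a [pearson_map()] result.
#' @param value `"p"` (default) or `"r"`.
#' @param stratum which stratum to export (default the first).
#' @return feature x miRNA numeric matrix, `NaN` for undefined pairs.
#' @export
heatmap_table <- function(map, value = c("p", "r"), stratum = NULL) {
  value <- match.arg(value)
  if (nrow(map) == 0) stop("empty correlation map")
  if (is.null(stratum)) stratum <- map$stratum[1]
  sub <- map[map$stratum == stratum, , drop = FALSE]
  feats <- unique(sub$feature)
  mirnas <- unique(sub$mirna)
  m <- matrix(NaN, nrow = length(feats), ncol = length(mirnas),
              dimnames = list(feats, mirnas))
  vals <- sub[[value]]
  vals[is.na(vals)] <- NaN
  m[cbind(match(sub$feature, feats), match(sub$mirna, mirnas))] <- vals
  m
}

#' Relative expression by the 2^-deltaCt method
#'
#' Converts RT-PCR cycle thresholds of a target and a housekeeping
#' reference into relative expression `2^-(ct_target - ct_reference)`.
#'
#' @param ct_target,ct_reference finite cycle-threshold values
#'   (vectorized).
#' @return Positive relative expression values.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}
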