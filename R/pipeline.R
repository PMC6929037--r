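#' Default pipeline configuration
#'
#' Builds the single configuration object driving [run_pipeline()]:
#' per-stage parameter blocks plus stage toggles. Stages run in order
#' simulate -> segment -> extract -> reduce -> associate -> evaluate; each
#' stage's outputs are the next stage's inputs. With `segment = FALSE` the
#' generator's truth masks are used directly.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed recorded in the manifest and used for every
#'   stage's randomness.
#' @param preset cohort preset for the simulate stage (see
#'   [cohort_config()]).
#' @param segment run region-growing segmentation (otherwise truth masks).
#' @param grow_fraction region-growing threshold fraction.
#' @param n_bins gray levels for feature extraction.
#' @param reduce_threshold absolute Spearman threshold for redundancy
#'   reduction.
#' @param panel `"auto"` or `"table5"` reduction panel.
#' @param alpha association significance level.
#' @param stratify_assoc compute associations within subtype strata.
#' @param n_repeats Monte Carlo CV repeats.
#' @param max_size largest signature size (1-3).
#' @param mirna_top,if_top caps on the signature pools (most significant
#'   first).
#' @param write_volumes also write all volumes/masks to disk (slower; off
#'   by default).
#' @return A `RunConfig` list.
#' @export
pipeline_config <- function(out_dir = tempfile("radiomir_run_"),
                            seed = 1L, preset = "brca1",
                            segment = TRUE, grow_fraction = 0.5,
                            n_bins = 32L, reduce_threshold = 0.8,
                            panel = "auto", alpha = 0.05,
                            stratify_assoc = TRUE,
                            n_repeats = 100L, max_size = 3L,
                            mirna_top = 3L, if_top = 2L,
                            write_volumes = FALSE) {
  list(out_dir = out_dir, seed = as.integer(seed), preset = preset,
       segment = isTRUE(segment), grow_fraction = grow_fraction,
       n_bins = as.integer(n_bins), reduce_threshold = reduce_threshold,
       panel = panel, alpha = alpha, stratify_assoc = isTRUE(stratify_assoc),
       n_repeats = as.integer(n_repeats), max_size = as.integer(max_size),
       mirna_top = as.integer(mirna_top), if_top = as.integer(if_top),
       write_volumes = isTRUE(write_volumes))
}

log_stage <- function(manifest, stage, t0, ...) {
  info <- list(...)
  elapsed <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] done in %.1fs%s", stage, elapsed,
                  if (length(info) > 0) {
                    paste0(" (", paste(names(info), unlist(info), sep = "=",
                                       collapse = ", "), ")")
                  } else ""))
  manifest$stages[[stage]] <- c(list(elapsed_s = elapsed), info)
  manifest
}

#' Run the full radiomiRNomic pipeline from one configuration
#'
#' Executes simulate -> (segment) -> extract -> reduce -> associate ->
#' evaluate on a synthetic cohort and writes every tabular artifact plus a
#' JSON run manifest (seed, parameters, artifact shapes, stage timings)
#' into `config$out_dir`. A stage failure aborts with the stage name; the
#' partially written manifest is kept with a `.partial` suffix.
#'
#' @param config a [pipeline_config()] (or a path to a JSON file holding
#'   one).
#' @return The manifest list, invisibly; artifacts on disk under
#'   `config$out_dir` (`features.csv`, `reduced.csv`, `associations.csv`,
#'   `ranking.csv`, `manifest.json`, ...).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("radiomiR")),
                   seed = config$seed, config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  partial <- file.path(config$out_dir, "manifest.json.partial")
  write_manifest <- function(path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
  }
  fail <- function(stage, e) {
    write_manifest(partial)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- simulate -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort <- tryCatch(
    generate_cohort(cohort_config(config$preset), seed = config$seed),
    error = function(e) fail("simulate", e))
  write_expression(cohort$expression, file.path(config$out_dir, "expression.tsv"))
  write_labels(cohort$labels, file.path(config$out_dir, "labels.csv"))
  if (config$write_volumes && !is.null(cohort$samples)) {
    write_cohort(cohort, config$out_dir)
  }
  manifest <- log_stage(manifest, "simulate", t0,
                        n_samples = nrow(cohort$labels),
                        n_mirnas = nrow(cohort$expression))

  if (is.null(cohort$samples)) {
    # expression-only preset: nothing to segment/extract; stop after assoc-free
    write_manifest(file.path(config$out_dir, "manifest.json"))
    return(invisible(manifest))
  }

  # -- segment --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  masks <- tryCatch({
    lapply(cohort$samples, function(s) {
      sub <- subtract_volumes(s$post, s$pre)
      if (config$segment) {
        seed_pt <- round(dim(sub$values) / 2)
        region_grow_segment(sub, seed_pt,
                            grow_fraction = config$grow_fraction)
      } else {
        s$truth
      }
    })
  }, error = function(e) fail("segment", e))
  dice <- mapply(function(m, s) {
    a <- m$values == 1L
    b <- s$truth$values == 1L
    2 * sum(a & b) / (sum(a) + sum(b))
  }, masks, cohort$samples)
  manifest <- log_stage(manifest, "segment", t0,
                        mode = if (config$segment) "region_growing" else "truth",
                        mean_dice_vs_truth = round(mean(dice), 4))

  # -- extract --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  features <- tryCatch({
    subs <- lapply(cohort$samples, function(s) subtract_volumes(s$post, s$pre))
    extract_feature_table(subs, masks, n_bins = config$n_bins)
  }, error = function(e) fail("extract", e))
  write_features(features, file.path(config$out_dir, "features.csv"))
  manifest <- log_stage(manifest, "extract", t0,
                        n_features = ncol(features) - 1L,
                        n_rows = nrow(features))

  # -- reduce ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  red <- tryCatch(
    reduce_features(features, threshold = config$reduce_threshold,
                    panel = config$panel),
    error = function(e) fail("reduce", e))
  write_features(red$reduced, file.path(config$out_dir, "reduced.csv"))
  jsonlite::write_json(
    list(panel = red$panel, threshold = red$threshold,
         representatives = red$representatives,
         clusters = lapply(red$clusters, identity), cv_flags = red$cv_flags),
    file.path(config$out_dir, "redundancy_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- log_stage(manifest, "reduce", t0,
                        n_representatives = length(red$representatives))

  # -- associate ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  assoc <- tryCatch({
    strat <- if (config$stratify_assoc) cohort$labels else NULL
    map <- pearson_map(red$reduced, cohort$expression, stratify = strat)
    flt <- filter_significant(map, alpha = config$alpha)
    list(map = map, flt = flt)
  }, error = function(e) fail("associate", e))
  map_out <- assoc$map
  map_out$retained <- !is.na(map_out$p) & map_out$p < config$alpha
  utils::write.csv(map_out, file.path(config$out_dir, "associations.csv"),
                   row.names = FALSE)
  manifest <- log_stage(manifest, "associate", t0,
                        n_pairs = nrow(assoc$map),
                        n_retained = nrow(assoc$flt$retained))

  # -- evaluate -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ranking <- tryCatch({
    ret <- assoc$flt$retained
    pool_rank <- function(ids) {
      if (length(ids) == 0) return(character(0))
      best_p <- vapply(ids, function(i) min(ret$p[ret$mirna == i | ret$feature == i]),
                       numeric(1))
      ids[order(best_p)]
    }
    mirna_pool <- pool_rank(unique(ret$mirna))
    if_pool <- pool_rank(unique(ret$feature))
    mirna_pool <- utils::head(mirna_pool, config$mirna_top)
    if_pool <- utils::head(if_pool, config$if_top)
    combined <- cbind(red$reduced,
                      as.data.frame(t(cohort$expression[, red$reduced$sample_id,
                                                        drop = FALSE])))
    enumerate_signatures(mirna_pool, if_pool, combined,
                         cohort$labels$subtype,
                         cv_config(n_repeats = config$n_repeats,
                                   seed = derive_seed(config$seed, 7L)),
                         max_size = config$max_size)
  }, error = function(e) fail("evaluate", e))
  utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                   row.names = FALSE)
  manifest <- log_stage(manifest, "evaluate", t0,
                        n_signatures = nrow(ranking),
                        best_signature = if (nrow(ranking) > 0) ranking$signature[1] else NA,
                        best_mean_auc = if (nrow(ranking) > 0) round(ranking$mean_auc[1], 4) else NA)

  write_manifest(file.path(config$out_dir, "manifest.json"))
  if (file.exists(partial)) unlink(partial)
  invisible(manifest)
}

#' Create a ready-to-run demo workspace
#'
#' Writes the default 37-sample synthetic cohort (expression, labels,
#' features on truth masks) and a pipeline configuration JSON into `dir`,
#' so that `run_pipeline(file.path(dir, "config.json"))` reproduces the
#' full analysis.
#'
#' @param dir writable target directory.
#' @param seed master seed stored in the config.
#' @param n_repeats Monte Carlo repeats recorded in the config.
#' @return Invisibly, a list with the config path and cohort summary.
#' @export
make_demo <- function(dir, seed = 17L, n_repeats = 100L) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create demo directory: ", dir)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("demo directory is not writable: ", dir)
  unlink(probe)
  cohort <- generate_cohort(cohort_config("brca1"), seed = seed)
  write_cohort(cohort, file.path(dir, "cohort"))
  config <- pipeline_config(out_dir = file.path(dir, "run"), seed = seed,
                            n_repeats = n_repeats)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(config = cfg_path,
                 n_samples = nrow(cohort$labels),
                 n_luminal_a = sum(cohort$labels$subtype == "LuminalA")))
}
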