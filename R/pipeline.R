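# End-to-end screen pipeline: design -> rasterize -> descriptors ->
# simulate -> quantify -> hits -> tree model -> recovery report, with
# per-stage seeds, cached preparation and a hashed run manifest.

#' Default pipeline configuration
#'
#' @param n_designs Non-flat library size (default 2175, a full chip).
#' @param rows,cols Chip grid (default 66 x 66).
#' @param seeds Named seeds per stage: `library`, `layout`, `simulation`,
#'   `split`, `tree`, `fcpn`.
#' @param resolution Raster resolution, micrometres per pixel.
#' @param count_range,size_ranges Library generation parameters.
#' @param mfi_cutoff TGM1 positivity cutoff.
#' @param hit_metric Unit metric the model is trained on.
#' @param k_top,k_bottom SD multiples for hit calling on `hit_metric`
#'   (`NULL` = metric defaults, see [default_hit_k()]).
#' @param tree Tree hyperparameters: `min_leaf`, `max_depth`, `cv_folds`.
#' @param planted_model A `planted_model`, a path to one, or `NULL` for
#'   [default_planted_model()].
#' @param images Render and quantify a subsample of units from images
#'   instead of consuming the simulated cell table directly.
#' @param image_units Subsample size in image mode.
#' @param noise_sd Image noise standard deviation in image mode.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param cache_dir Directory for the reusable library/descriptor stage
#'   (`NULL` = recompute in memory).
#' @param verbose Progress messages.
#' @return A list of class `run_config`.
#' @export
default_config <- function(n_designs = 2175, rows = 66, cols = 66,
                           seeds = list(library = 11, layout = 12,
                                        simulation = 13, split = 14,
                                        tree = 15, fcpn = 101),
                           resolution = 0.5, count_range = c(1, 30),
                           size_ranges = default_size_ranges(),
                           mfi_cutoff = 270,
                           hit_metric = "avg_spread_area_pos",
                           k_top = NULL, k_bottom = NULL,
                           tree = list(min_leaf = 8, max_depth = 5,
                                       cv_folds = 10),
                           planted_model = NULL, images = FALSE,
                           image_units = 200, noise_sd = 10,
                           out_dir = NULL, cache_dir = NULL,
                           verbose = FALSE) {
  cfg <- as.list(environment())
  base_seeds <- list(library = 11, layout = 12, simulation = 13, split = 14,
                     tree = 15, fcpn = 101)
  cfg$seeds <- utils::modifyList(base_seeds, as.list(seeds))
  base_tree <- list(min_leaf = 8, max_depth = 5, cv_folds = 10)
  cfg$tree <- utils::modifyList(base_tree, as.list(tree))
  structure(cfg, class = "run_config")
}

#' Read a run configuration file (YAML or JSON)
#'
#' Keys missing from the file fall back to [default_config()] values.
#'
#' @param path Configuration file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else
    yaml::read_yaml(path)
  known <- names(formals(default_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(default_config, raw)
}

resolve_planted <- function(config) {
  pm <- config$planted_model
  if (is.null(pm)) return(default_planted_model())
  if (inherits(pm, "planted_model")) return(pm)
  if (is.character(pm)) {
    if (!file.exists(pm)) stopf("planted model file '%s' does not exist", pm)
    return(read_planted_model(pm))
  }
  stopf("planted_model must be NULL, a planted_model or a file path")
}

#' Write / read a chip layout (JSON)
#' @param layout A `chip_layout`.
#' @param path File path.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(rows = x$rows, cols = x$cols, offset = x$offset,
                 n_designs = x$n_designs,
                 cells = quick_df(as.list(x$cells))),
            class = "chip_layout")
}

prep_signature <- function(config) {
  key <- list(n_designs = config$n_designs, rows = config$rows,
              cols = config$cols,
              seeds = config$seeds[c("library", "layout", "fcpn")],
              resolution = config$resolution,
              count_range = config$count_range,
              size_ranges = config$size_ranges)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Prepare the chip: library, layout and descriptors
#'
#' This is the expensive, simulation-independent part of a run; when
#' `cache_dir` is set, results are written there together with a parameter
#' signature and reused by later calls with the same parameters.
#'
#' @param config A `run_config`.
#' @param cache_dir Cache directory (default from the config).
#' @return A list `library`, `layout`, `descriptors`.
#' @export
prepare_chip <- function(config = default_config(),
                         cache_dir = config$cache_dir) {
  sig <- prep_signature(config)
  if (!is.null(cache_dir)) {
    sigfile <- file.path(cache_dir, "prep.sig")
    files <- file.path(cache_dir, c("lib.json", "layout.json", "features.csv"))
    if (file.exists(sigfile) && all(file.exists(files)) &&
        readLines(sigfile, n = 1L) == sig) {
      if (isTRUE(config$verbose)) message("prepare_chip: reusing cache")
      return(list(library = read_designs(files[1]),
                  layout = read_layout(files[2]),
                  descriptors = read_descriptors(files[3])))
    }
  }
  if (isTRUE(config$verbose)) message("prepare_chip: generating library")
  library <- generate_library(config$n_designs, seed = config$seeds$library,
                              size_ranges = config$size_ranges,
                              count_range = config$count_range)
  layout <- layout_chip(library, rows = config$rows, cols = config$cols,
                        seed = config$seeds$layout)
  dcfg <- descriptor_config(resolution = config$resolution,
                            fcpn_seed = config$seeds$fcpn)
  descriptors <- library_descriptors(library, dcfg,
                                     verbose = isTRUE(config$verbose))
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    write_designs(library, file.path(cache_dir, "lib.json"))
    write_layout(layout, file.path(cache_dir, "layout.json"))
    write_descriptors(descriptors, file.path(cache_dir, "features.csv"))
    writeLines(sig, file.path(cache_dir, "prep.sig"))
  }
  list(library = library, layout = layout, descriptors = descriptors)
}

# image-mode quantification of a subsample of units
analyze_units_from_images <- function(cells, keys, resolution, noise_sd,
                                      seed, cutoff, unit_side = 300) {
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- cells$row == keys$row[i] & cells$col == keys$col[i] &
      cells$chip_id == keys$chip_id[i]
    uc <- cells[sel, , drop = FALSE]
    stack <- render_unit(uc, resolution = resolution, unit_side = unit_side,
                         noise_sd = noise_sd, seed = seed + i)
    measured <- analyze_stack(stack, cutoff = cutoff)
    s <- summarize_unit(measured)
    rows[[i]] <- cbind(keys[i, , drop = FALSE], s)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Fit and evaluate the hit-classification model of a screen
#'
#' Calls hits on the configured metric, labels designs (either-duplicate
#' rule), joins the descriptor table (absent descriptor values are imputed
#' as 0, meaning "no such primitive"), eliminates correlated features,
#' splits 75/25 stratified, fits the cross-validated tree and reports the
#' held-out ROC/AUC and the planted-structure recovery.
#'
#' @param units Unit summary table (with `design_id`).
#' @param descriptors Descriptor table.
#' @param planted A `planted_model` (for the recovery report).
#' @param config A `run_config` (metric, k values, seeds, tree settings).
#' @return A list of class `screen_model`: `hits`, `labels`, `filter`,
#'   `tree`, `roc`, `recovery`, `split`.
#' @export
screen_model <- function(units, descriptors, planted,
                         config = default_config()) {
  metric <- config$hit_metric
  k <- default_hit_k(metric)
  k_top <- config$k_top %||% k[1]
  k_bottom <- config$k_bottom %||% k[2]
  hits <- select_hits(units, metric, k_top = k_top, k_bottom = k_bottom)
  labels <- make_labels(hits)
  feature_cols <- setdiff(names(descriptors), "design_id")
  feats <- descriptors
  imputed <- character(0)
  for (f in feature_cols) {
    if (anyNA(feats[[f]])) {
      imputed <- c(imputed, f)
      feats[[f]][is.na(feats[[f]])] <- 0
    }
  }
  ftab <- merge(labels, feats, by = "design_id", sort = TRUE)
  filt <- filter_correlated(ftab, r2_max = 0.75, feature_cols = feature_cols)
  sp <- split_train_test(filt$table, frac = 0.75,
                         seed = config$seeds$split)
  tree <- fit_tree(sp$train, feature_cols = filt$kept,
                   min_leaf = config$tree$min_leaf,
                   max_depth = config$tree$max_depth,
                   cv_folds = config$tree$cv_folds,
                   seed = config$seeds$tree)
  scores <- predict(tree, sp$test)
  roc <- roc_auc(scores, sp$test$label)
  recovery <- evaluate_recovery(tree, planted, auc = roc$auc)
  structure(list(hits = hits, labels = labels, filter = filt,
                 imputed = imputed, split = sp, tree = tree, roc = roc,
                 recovery = recovery),
            class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf("screen_model: %d high / %d low designs, AUC %.3f, recovered %s\n",
              sum(x$labels$label == "high"), sum(x$labels$label == "low"),
              x$roc$auc, x$recovery$recovered))
  invisible(x)
}

#' Run the whole screen pipeline
#'
#' Executes library generation, layout, descriptor extraction, screen
#' simulation under the planted model, quantification (cell table by
#' default; rendered-image quantification of a unit subsample in image
#' mode), hit selection, tree modelling and recovery evaluation. All
#' randomness is controlled by the per-stage seeds of the configuration,
#' so identical configurations give identical outputs and manifests.
#'
#' @param config A `run_config`.
#' @param prep Optional precomputed [prepare_chip()] result.
#' @return A list of class `toposcreen_run` with all stage outputs and the
#'   manifest (written to `out_dir` along with the stage files when set).
#' @export
run_pipeline <- function(config = default_config(), prep = NULL) {
  planted <- resolve_planted(config)  # config errors surface before compute
  if (is.null(prep)) prep <- prepare_chip(config)
  if (isTRUE(config$verbose)) message("simulating screen")
  screen <- simulate_screen(prep$library, prep$layout, planted,
                            prep$descriptors,
                            seed = config$seeds$simulation,
                            positions = isTRUE(config$images))
  cells <- classify_tgm1(screen$cells, cutoff = config$mfi_cutoff)
  units <- summarize_units(cells)
  if (isTRUE(config$images)) {
    n_img <- min(config$image_units, nrow(units))
    keys <- units[seq_len(n_img), c("chip_id", "row", "col", "design_id"),
                  drop = FALSE]
    img_units <- analyze_units_from_images(
      cells, keys, resolution = config$resolution,
      noise_sd = config$noise_sd, seed = config$seeds$simulation,
      cutoff = config$mfi_cutoff)
    key_all <- paste(units$chip_id, units$row, units$col)
    key_img <- paste(img_units$chip_id, img_units$row, img_units$col)
    units[match(key_img, key_all), names(img_units)] <- img_units
  }
  if (isTRUE(config$verbose)) message("fitting model")
  model <- screen_model(units, prep$descriptors, planted, config)
  run <- structure(list(config = config, library = prep$library,
                        layout = prep$layout,
                        descriptors = prep$descriptors, screen = screen,
                        cells = cells, units = units, model = model),
                   class = "toposcreen_run")
  run$manifest <- build_manifest(run)
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

manifest_config <- function(config) {
  config[c("n_designs", "rows", "cols", "seeds", "resolution",
           "count_range", "mfi_cutoff", "hit_metric", "tree", "images",
           "image_units", "noise_sd")]
}

build_manifest <- function(run) {
  m <- run$model
  list(package = "toposcreen",
       version = as.character(utils::packageVersion("toposcreen")),
       config = manifest_config(run$config),
       stats = list(
         n_designs = run$layout$n_designs,
         n_units = nrow(run$screen$truth),
         n_cells = nrow(run$cells),
         n_high_designs = sum(m$labels$label == "high"),
         n_low_designs = sum(m$labels$label == "low"),
         dropped_features = m$filter$dropped$feature,
         tree_leaves = sum(is.na(m$tree$nodes$feature)),
         auc = m$roc$auc),
       recovery = list(recovered = m$recovery$recovered,
                       top_features = m$recovery$top_features,
                       planted_features = m$recovery$planted_features))
}

#' Write a run's stage outputs and manifest to a directory
#'
#' Emits `lib.json`, `layout.json`, `features.csv`, `cells.csv`,
#' `truth.csv`, `units.csv`, `hits.csv`, `labels.csv`, `model.json`,
#' `report.json` and `manifest.json` (the manifest records the
#' configuration and the MD5 hash of every other file).
#'
#' @param run A `toposcreen_run`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_designs(run$library, p("lib.json"))
  write_layout(run$layout, p("layout.json"))
  write_descriptors(run$descriptors, p("features.csv"))
  utils::write.csv(run$cells, p("cells.csv"), row.names = FALSE, na = "")
  utils::write.csv(run$screen$truth, p("truth.csv"), row.names = FALSE, na = "")
  utils::write.csv(run$units, p("units.csv"), row.names = FALSE, na = "")
  hits <- run$model$hits
  hits_out <- as.data.frame(hits)
  hits_out$metric <- attr(hits, "metric")
  hits_out$top_cutoff <- attr(hits, "top_cutoff")
  hits_out$bottom_cutoff <- attr(hits, "bottom_cutoff")
  utils::write.csv(hits_out, p("hits.csv"), row.names = FALSE, na = "")
  utils::write.csv(run$model$labels, p("labels.csv"), row.names = FALSE)
  write_tree(run$model$tree, p("model.json"))
  jsonlite::write_json(
    list(auc = run$model$roc$auc, roc = run$model$roc$roc,
         dropped_features = run$model$filter$dropped,
         imputed_features = run$model$imputed,
         recovery = unclass(run$model$recovery)),
    p("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  files <- c("lib.json", "layout.json", "features.csv", "cells.csv",
             "truth.csv", "units.csv", "hits.csv", "labels.csv",
             "model.json", "report.json")
  manifest <- run$manifest
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(out_dir, files))), files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}

#' @export
print.toposcreen_run <- function(x, ...) {
  s <- x$manifest$stats
  cat(sprintf(
    "toposcreen_run: %d designs, %d units, %d cells\n  %d high / %d low designs, tree with %d leaves, held-out AUC %.3f\n  recovered planted features: %s\n",
    s$n_designs, s$n_units, s$n_cells, s$n_high_designs, s$n_low_designs,
    s$tree_leaves, s$auc, x$manifest$recovery$recovered))
  invisible(x)
}
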