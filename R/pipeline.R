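# Config-driven orchestration of the full pipeline:
# augment -> train both streams -> extract -> fuse -> select -> evaluate ->
# explain, with stage caching, JSON-lines logging and a summary artifact.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]. All
#' fields have defaults; `config` may be a partial named list (e.g. parsed
#' from YAML with [yaml::read_yaml()]), whose entries override the defaults.
#' The configuration round-trips losslessly through its YAML form.
#'
#' @param config Optional named list (or path to a YAML file) of overrides.
#' @param ... Individual overrides (take precedence over `config`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    data = list(kind = "synthetic", n_classes = 5L, per_class = 30L,
                image_size = 64L, separation = 1),
    input_size = 64L,
    feature_dim = 1024L,
    seed = 1L,
    train = list(mini_batch = 16L, learning_rate = 1e-4, epochs = 10L,
                 momentum = 0.9),
    augment = list(),
    fusion = list(bins = 256L),
    bco = list(enabled = TRUE, pop = 20L, T_max = 50L, alpha = 0.99,
               fitness_classifier = "knn"),
    presets = c("NNN", "MNN", "WNN", "BNN", "TNN"),
    folds = 10L,
    gradcam_examples = 0L
  )
  override <- utils::modifyList(config %||% list(), list(...))
  cfg <- utils::modifyList(defaults, override)
  if (is.null(cfg$out_dir)) stop("config needs an out_dir", call. = FALSE)
  stopifnot(cfg$folds >= 2L, all(cfg$presets %in% names(.preset_widths)))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# content hash of an R object (used for stage keys and provenance logs)
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

# immutable cached stage: recompute only when the key changes
.stage <- function(run, name, key, fn) {
  cache <- file.path(run$dir, "cache")
  dir.create(cache, showWarnings = FALSE, recursive = TRUE)
  hash <- .hash_obj(key)
  path <- file.path(cache, sprintf("%s_%s.rds", name, hash))
  cached <- file.exists(path)
  t0 <- proc.time()[["elapsed"]]
  out <- if (cached) readRDS(path) else {
    val <- fn()
    saveRDS(val, path)
    val
  }
  entry <- list(stage = name, key = hash, cached = cached,
                seconds = round(proc.time()[["elapsed"]] - t0, 2),
                artifact = basename(path))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(run$dir, "log.jsonl"), append = TRUE, sep = "")
  out
}

#' Run the full classification pipeline
#'
#' Executes every stage in order: dataset preparation (synthetic generation
#' or manifest loading), train-split augmentation, training of the residual
#' and inverted-residual streams, deep-feature extraction for both splits,
#' serial fusion (with optional entropy reduction), binary-ChOA feature
#' selection on the train-split fused features, and cross-validated
#' evaluation of every classifier preset on four feature configurations
#' (residual, inverted, fused, selected) over the held-out test split.
#' Training and feature selection never see test-split records (audited and
#' logged); stage outputs are cached by content hash, so a rerun with an
#' unchanged config reuses them.
#'
#' @param config A [pipeline_config] (or a list / YAML path accepted by it).
#' @return The summary list, also written to `out_dir/summary.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- list(dir = config$out_dir)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

  manifest <- .stage(run, "data", config[c("data", "seed")], function() {
    d <- config$data
    if (identical(d$kind, "synthetic")) {
      generate_leaf_dataset(default_leaf_specs(d$n_classes, d$separation),
                            rep(d$per_class, d$n_classes),
                            dir = file.path(config$out_dir, "data"),
                            image_size = d$image_size, seed = config$seed,
                            keep_masks = TRUE)
    } else {
      read_manifest(d$manifest)
    }
  })

  if (!is.null(config$augment$target_per_class)) {
    manifest <- .stage(run, "augment",
                       list(config$data, config$augment, config$seed),
                       function() augment_to_target(
                         manifest, config$augment$target_per_class,
                         seed = config$seed, split = "train"))
  }

  tconf <- do.call(train_config, c(config$train, list(seed = config$seed)))
  n_classes <- length(attr(manifest, "class_names"))
  nets <- list()
  graphs <- list(residual = build_residual_net(n_classes, config$feature_dim),
                 inverted_residual = build_inverted_residual_net(n_classes, config$feature_dim))
  for (nm in names(graphs)) {
    nets[[nm]] <- .stage(run, paste0("train_", nm),
                         list(config$data, config$augment, tconf,
                              config$input_size, nm),
                         function() train_network(graphs[[nm]], manifest, tconf,
                                                  input_size = config$input_size))
  }

  feats <- .stage(run, "features",
                  list(config$data, config$augment, tconf, config$input_size,
                       config$feature_dim),
                  function() {
    out <- list()
    for (split in c("train", "test")) {
      im <- load_images(manifest, split = split, input_size = config$input_size)
      out[[split]] <- lapply(nets, function(net) {
        fm <- extract_features(net, im$x, labels = im$labels)
        fm$row_ids <- im$rows$path
        fm
      })
    }
    out
  })

  fuse_one <- function(split) {
    fm <- serial_fuse(feats[[split]]$residual, feats[[split]]$inverted_residual)
    if (!is.null(config$fusion$keep))
      fm <- entropy_rank(fm, keep = config$fusion$keep, bins = config$fusion$bins)
    fm
  }
  fused <- list(train = fuse_one("train"), test = fuse_one("test"))

  selection <- NULL
  if (isTRUE(config$bco$enabled)) {
    selection <- .stage(run, "bco_select",
                        list(config$data, config$augment, tconf, config$bco,
                             config$fusion, config$input_size),
                        function() select_features(
                          fused$train, pop = config$bco$pop,
                          T_max = config$bco$T_max, seed = config$seed,
                          alpha = config$bco$alpha,
                          fitness_classifier = config$bco$fitness_classifier))
  }

  # leakage audit: training/selection inputs vs held-out evaluation records
  train_paths <- manifest$path[manifest$split == "train"]
  test_paths <- manifest$path[manifest$split == "test"]
  stopifnot(length(intersect(train_paths, test_paths)) == 0L)

  feature_sets <- list(residual = feats$test$residual,
                       inverted_residual = feats$test$inverted_residual,
                       fused = fused$test)
  if (!is.null(selection))
    feature_sets$selected <- subset_features(fused$test, selection$selected_idx)

  results <- .stage(run, "evaluate",
                    list(config$data, config$augment, tconf, config$bco,
                         config$fusion, config$presets, config$folds,
                         config$input_size),
                    function() {
    lapply(feature_sets, function(fm) {
      stats::setNames(lapply(config$presets, function(p)
        crossval_evaluate(fm, p, k = config$folds, seed = config$seed)),
        config$presets)
    })
  })

  if (config$gradcam_examples > 0L) {
    gc_dir <- file.path(config$out_dir, "gradcam")
    dir.create(gc_dir, showWarnings = FALSE)
    rows <- manifest[manifest$split == "test", ]
    rows <- rows[seq_len(min(config$gradcam_examples, nrow(rows))), ]
    for (i in seq_len(nrow(rows))) {
      img <- load_image(file.path(attr(manifest, "dir"), rows$path[i]))
      hm <- compute_gradcam(nets$residual, img, rows$label[i])
      gradcam_overlay(hm, img, file.path(gc_dir, sprintf("overlay_%03d.png", i)))
    }
  }

  summary <- list(
    seed = config$seed,
    class_names = attr(manifest, "class_names"),
    n_train = length(train_paths), n_test = length(test_paths),
    selection = if (!is.null(selection))
      list(selected_idx = selection$selected_idx,
           selected_count = selection$selected_count,
           final_fitness = selection$final_fitness,
           fitness_trace = selection$fitness_trace),
    results = lapply(results, function(by_preset)
      lapply(by_preset, function(r)
        list(accuracy = r$accuracy, precision = r$precision, recall = r$recall,
             f1 = r$f1, error = r$error, fnr = r$fnr,
             confusion = unclass(r$confusion), wall_time = r$wall_time)))
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
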