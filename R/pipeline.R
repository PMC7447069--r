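#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end run with the package defaults:
#' a synthetic default scene, two segmentation layers (a coarse
#' non-vegetation layer and a fine vegetation layer), the candidate filter,
#' sampling parameters, layer-1 membership rules and the classifier choice.
#' Segmentation band weights default to (blue, green, red, nir, dsm) =
#' (1, 1, 1, 2, 0.05): NIR carries double weight and the DSM layer — in
#' metres, not DN — is down-weighted so it refines but does not dominate the
#' colour heterogeneity.
#'
#' @param seed global seed; every stage derives its sub-seed from it.
#' @param scene list of [synth_scene()] arguments (synthetic input), or
#'   `NULL` when `paths` are supplied.
#' @param paths optional list with `dsm`, `bands` (4 ASCII-grid paths) and
#'   `mab` for real rasters.
#' @param seg1,seg2 [segmentation_params] for the two layers.
#' @param filter a [candidate_filter].
#' @param sampling a [sampling_params].
#' @param rules layer-1 membership rules.
#' @param classifier `"rf"` or `"knn"`.
#' @param tune if `TRUE`, grid-tune the classifier by macro-F1; otherwise
#'   use the shipped default parameters (RF: depth 19, 8 features/split,
#'   20 trees, leaf 2; KNN: k = 9).
#' @param n_validation validation points for the accuracy assessment.
#' @param label_noise training-label noise fraction (robustness experiments).
#' @param out_dir artifact directory or `NULL` to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            scene = list(rows = 512L, cols = 512L),
                            paths = NULL,
                            seg1 = segmentation_params(
                              scale = 60, shape_factor = 0.2,
                              compactness = 0.6,
                              band_weights = c(1, 1, 1, 2, 0.05)),
                            seg2 = segmentation_params(
                              scale = 12, shape_factor = 0.2,
                              compactness = 0.6,
                              band_weights = c(1, 1, 1, 2, 0.05)),
                            filter = candidate_filter(min_area = 5),
                            sampling = sampling_params(),
                            rules = default_membership_rules(),
                            classifier = "rf", tune = FALSE,
                            n_validation = 1000L, label_noise = 0,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), scene = scene, paths = paths,
                 seg1 = seg1, seg2 = seg2, filter = filter,
                 sampling = sampling, rules = rules,
                 classifier = match.arg(classifier, c("rf", "knn")),
                 tune = tune, n_validation = as.integer(n_validation),
                 label_noise = label_noise, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash_ <- function(config) {
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Run the full pipeline
#'
#' Synthesize (or load) the scene, segment both layers, mask non-vegetation
#' with the fuzzy membership rules, stratify by slope and belt, select and
#' correct samples automatically, train the classifier and assess accuracy.
#' Deterministic for a fixed config: re-running reproduces every artifact.
#'
#' @param config a [pipeline_config].
#' @return a `pipeline_report` list: per-stage outputs (`scene`, `objects`,
#'   `features`, `veg`, `belts`, `sample_db`, `classification`,
#'   `evaluation`) plus `seeds`, `config_hash` and `timings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[[3L]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[[3L]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  seed <- config$seed

  # ---- scene -------------------------------------------------------------
  if (!is.null(config$paths)) {
    dsm <- read_ascii_grid(config$paths$dsm)
    bands <- lapply(config$paths$bands, read_ascii_grid)
    image <- array(unlist(bands), c(dim(dsm), 4),
                   dimnames = list(NULL, NULL, bands_))
    table <- load_mab_table(config$paths$mab)
    scene <- list(dsm = dsm, image = image, truth = NULL,
                  legend = scene_legend_(table), table = table,
                  signatures = default_signatures())
  } else {
    scene <- do.call(synth_scene, c(config$scene, list(seed = seed)))
  }
  table <- scene$table
  tick("scene")

  stack <- c(lapply(1:4, function(b) scene$image[, , b]),
             list(dsm = scene$dsm))
  names(stack) <- c(bands_, "dsm")

  # ---- segmentation (two layers) -----------------------------------------
  l1 <- segment(stack, config$seg1)
  l2 <- segment(stack, config$seg2)
  tick("segment")

  f1 <- compute_features(l1, scene$image, scene$dsm)
  f2 <- compute_features(l2, scene$image, scene$dsm)
  tick("features")

  # ---- layer 1: non-vegetation mask, inherited by layer 2 ----------------
  l1_labels <- classify_layer1(f1, config$rules)
  veg2 <- inherit_classes(l1_labels, l1, l2)
  tick("layer1")

  # ---- terrain constraint factors ----------------------------------------
  slopes <- split_slopes(scene$dsm)
  belts <- build_constraint_raster(scene$dsm, slopes, table)
  belt_assign <- assign_objects(l2, belts)
  tick("stratify")

  # ---- automatic sample selection ----------------------------------------
  prototypes <- prototypes_from_signatures(scene$signatures)
  db <- build_sample_db(f2, belt_assign, table, prototypes,
                        veg_object = veg2 == "vegetation",
                        params = config$sampling, filter = config$filter,
                        seed = seed + 10L)
  tick("sampling")

  # ---- feature selection + classification --------------------------------
  pool <- do.call(rbind, lapply(db$sets, function(s) {
    data.frame(object_id = s$ids, class = s$formation,
               stringsAsFactors = FALSE)
  }))
  rankable <- c(clustering_features(), "glcm_contrast", "glcm_entropy",
                "dsm_mean", "area", "length_width")
  xr <- as.matrix(f2[match(pool$object_id, f2$object_id), rankable])
  xr[!is.finite(xr)] <- 0
  ranking <- rank_features(xr, pool$class, seed = seed + 20L)
  feats <- select_top_features(ranking)

  spec <- if (config$tune) {
    tune_classifier(config$classifier, xr[, feats], pool$class,
                    seed = seed + 21L)
  } else if (config$classifier == "rf") {
    list(kind = "rf", params = data.frame(max_depth = 19L, max_features = 8L,
                                          n_estimators = 20L,
                                          min_samples_leaf = 2L))
  } else {
    list(kind = "knn", params = data.frame(n_neighbors = 9L))
  }
  spec$params$max_features <- min(spec$params$max_features, length(feats))
  cls <- train_classify(spec, db, f2, veg2, feats,
                        target_n = config$sampling$target_n,
                        label_noise = config$label_noise, seed = seed + 30L)
  tick("classify")

  # ---- rasterize + evaluate ----------------------------------------------
  pred_raster <- matrix(cls$object_labels[as.numeric(l2$labels)],
                        nrow(scene$dsm))
  evaluation <- NULL
  if (!is.null(scene$truth)) {
    ref_raster <- matrix(scene$legend$class[scene$truth], nrow(scene$dsm))
    classes <- scene$legend$class
    vp <- validation_points(pred_raster, ref_raster,
                            n = min(config$n_validation,
                                    sum(!is.na(ref_raster))),
                            classes = classes, seed = seed + 40L)
    truth_class <- scene$legend$class[majority_labels_(l2, scene$truth)]
    sar <- sample_accuracy_report(db, truth_class, f2, l2)
    evaluation <- list(
      confusion = vp$confusion,
      overall_accuracy = overall_accuracy(vp$confusion),
      kappa = kappa(vp$confusion),
      user_accuracy = vapply(classes, function(cl)
        as.numeric(user_accuracy(vp$confusion, cl)), numeric(1)),
      producer_accuracy = vapply(classes, function(cl)
        as.numeric(producer_accuracy(vp$confusion, cl)), numeric(1)),
      n_error_points = nrow(vp$error_points),
      error_points = vp$error_points,
      sample_accuracy = sar)
  }
  tick("evaluate")

  report <- structure(list(
    scene = scene, layer1 = l1, objects = l2, features = f2,
    layer1_features = f1, veg = veg2, slopes = slopes, belts = belts,
    belt_assign = belt_assign, sample_db = db, ranking = ranking,
    selected_features = feats, classifier_spec = spec,
    classification = cls, pred_raster = pred_raster,
    evaluation = evaluation, seeds = list(master = seed),
    config = config, config_hash = config_hash_(config),
    timings = timings), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_artifacts_(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("vegbelt pipeline report (config", x$config_hash, ")\n")
  cat(sprintf("  objects: layer1 %d, layer2 %d\n", x$layer1$n_objects,
              x$objects$n_objects))
  cat(sprintf("  sample sets: %d (of %d belts)\n",
              length(x$sample_db$sets), nrow(x$sample_db$report)))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  overall accuracy %.1f%%, kappa %.3f, %d error points\n",
                100 * x$evaluation$overall_accuracy, x$evaluation$kappa,
                x$evaluation$n_error_points))
    cat(sprintf("  mean sample accuracy %.3f\n",
                attr(x$evaluation$sample_accuracy, "summary")$overall))
  }
  invisible(x)
}

write_artifacts_ <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_ascii_grid(report$scene$dsm, p("dsm.asc"))
  write_ascii_grid(report$objects$labels, p("objects_layer2.asc"))
  write_ascii_grid(report$belts$belt_ids, p("belts.asc"))
  utils::write.csv(report$belts$legend, p("belt_legend.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, p("features_layer2.csv"),
                   row.names = FALSE)
  pred_id <- matrix(match(report$pred_raster, report$scene$legend$class),
                    nrow(report$pred_raster))
  write_ascii_grid(pred_id, p("classification.asc"))
  utils::write.csv(report$scene$legend, p("class_legend.csv"),
                   row.names = FALSE)
  # sample centroids with provenance
  cc <- as.numeric(col(report$objects$labels))
  rr <- as.numeric(row(report$objects$labels))
  grp <- factor(as.numeric(report$objects$labels),
                levels = seq_len(report$objects$n_objects))
  ox <- as.numeric(tapply(cc, grp, mean))
  oy <- as.numeric(tapply(rr, grp, mean))
  samp <- do.call(rbind, lapply(names(report$sample_db$sets), function(nm) {
    s <- report$sample_db$sets[[nm]]
    data.frame(x = ox[s$ids], y = oy[s$ids], object_id = s$ids,
               formation = s$formation, slope = s$slope, stage = s$stage)
  }))
  if (!is.null(samp)) write_geojson_points(samp, p("samples.geojson"))
  meta <- list(seed = report$seeds$master, config_hash = report$config_hash,
               timings = as.list(report$timings))
  if (!is.null(report$evaluation)) {
    ev <- report$evaluation
    utils::write.csv(as.data.frame(unclass(ev$confusion)),
                     p("confusion.csv"))
    if (nrow(ev$error_points)) {
      write_geojson_points(
        data.frame(x = ev$error_points$col, y = ev$error_points$row,
                   pred = ev$error_points$pred, ref = ev$error_points$ref),
        p("error_points.geojson"))
    }
    meta$overall_accuracy <- ev$overall_accuracy
    meta$kappa <- ev$kappa
    meta$mean_sample_accuracy <-
      attr(ev$sample_accuracy, "summary")$overall
  }
  jsonlite::write_json(meta, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
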