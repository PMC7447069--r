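#' Fuzzy membership rules
#'
#' A membership rule maps a feature value to a non-vegetation membership in
#' `[0, 1]`: 1 on the "full" side, 0 beyond the "zero" threshold, and a
#' smooth cosine Z-ramp on the transition interval (monotone, value 0.5 at
#' the midpoint). `full < zero` gives a decreasing ramp (e.g. NDVI x 100
#' fully non-vegetation below -2, fully vegetation above 1); `full > zero`
#' mirrors it (e.g. brightness: bright objects are non-vegetation).
#'
#' @param variable one of `"ndvi100"`, `"brightness"`, `"dsm"` (the feature
#'   the rule reads).
#' @param full value at (and beyond) which membership is 1.
#' @param zero value at (and beyond) which membership is 0.
#' @return a `membership_rule`.
#' @export
membership_rule <- function(variable, full, zero) {
  variable <- match.arg(variable, c("ndvi100", "brightness", "dsm"))
  stopifnot(is.numeric(full), is.numeric(zero), full != zero)
  structure(list(variable = variable, full = full, zero = zero),
            class = "membership_rule")
}

#' @rdname membership_rule
#' @param value numeric vector of feature values.
#' @param rule a `membership_rule`.
#' @return membership values in `[0, 1]`.
#' @export
membership <- function(value, rule) {
  stopifnot(inherits(rule, "membership_rule"))
  f <- rule$full; z <- rule$zero
  t <- (value - f) / (z - f) # 0 at full, 1 at zero, sign-free
  t <- pmin(pmax(t, 0), 1)
  0.5 + 0.5 * cos(pi * t)
}

#' Default layer-1 membership rules for the synthetic scene
#'
#' NDVI x 100 uses the published interval (-2, 1); the brightness and DSM
#' endpoints are calibrated on the synthetic signatures (non-vegetation is
#' bright and lies in the basal zone; the DSM rule keeps bright high-altitude
#' snow-like objects out of the non-vegetation class).
#'
#' @return named list of [membership_rule]s (`ndvi100`, `brightness`, `dsm`).
#' @export
default_membership_rules <- function() {
  list(ndvi100 = membership_rule("ndvi100", full = -2, zero = 1),
       brightness = membership_rule("brightness", full = 100, zero = 85),
       dsm = membership_rule("dsm", full = 850, zero = 1000))
}

#' Layer-1 vegetation / non-vegetation classification
#'
#' The non-vegetation membership of an object is the minimum (fuzzy AND) of
#' its NDVI x 100, brightness and DSM rule memberships; an object is
#' non-vegetation iff that combined membership is at least `cutoff`.
#'
#' @param features feature table (needs `ndvi`, `brightness`, `dsm_mean`).
#' @param rules named list of rules as in [default_membership_rules()].
#' @param cutoff decision threshold (default 0.5, `>=` convention).
#' @return character vector `"vegetation"`/`"non-vegetation"` per object,
#'   with the combined membership as attribute `"membership"`.
#' @export
classify_layer1 <- function(features, rules = default_membership_rules(),
                            cutoff = 0.5) {
  need <- c("ndvi", "brightness", "dsm_mean")
  if (!all(need %in% names(features))) {
    stop("feature table lacks: ",
         paste(setdiff(need, names(features)), collapse = ", "))
  }
  stopifnot(all(c("ndvi100", "brightness", "dsm") %in% names(rules)))
  m <- pmin(membership(100 * features$ndvi, rules$ndvi100),
            membership(features$brightness, rules$brightness),
            membership(features$dsm_mean, rules$dsm))
  out <- ifelse(m >= cutoff, "non-vegetation", "vegetation")
  attr(out, "membership") <- m
  out
}

#' Inherit layer-1 classes onto layer-2 objects
#'
#' Each layer-2 object takes the layer-1 label covering the majority of its
#' pixels; an exact 50/50 tie goes to "vegetation" so the object continues
#' to the formation classifier.
#'
#' @param layer1_labels character labels per layer-1 object.
#' @param layer1_objects,layer2_objects `object_map`s on the same grid.
#' @return character label per layer-2 object.
#' @export
inherit_classes <- function(layer1_labels, layer1_objects, layer2_objects) {
  stopifnot(identical(dim(layer1_objects$labels),
                      dim(layer2_objects$labels)))
  l1pix <- layer1_labels[as.numeric(layer1_objects$labels)]
  nonveg <- matrix(as.integer(l1pix == "non-vegetation"),
                   nrow(layer1_objects$labels))
  frac <- as.numeric(tapply(as.numeric(nonveg),
                            factor(as.numeric(layer2_objects$labels),
                                   levels = seq_len(layer2_objects$n_objects)),
                            mean))
  ifelse(frac > 0.5, "non-vegetation", "vegetation")
}

#' Rank features by random-forest importance
#'
#' Impurity-based importances from a default-parameter forest, normalized to
#' sum 1 and sorted descending. [select_top_features()] keeps the top
#' `min(8, k)` features where `k` is the smallest count reaching 95%
#' cumulative importance.
#'
#' @param x labelled feature matrix (rows = samples).
#' @param y class labels (>= 2 classes).
#' @param seed integer seed.
#' @return data.frame `feature`, `importance` (descending).
#' @export
rank_features <- function(x, y, seed = 1L) {
  y <- factor_c_(y)
  if (nlevels(y) < 2L) stop("feature ranking needs at least 2 classes")
  model <- rf_fit(x, y, n_estimators = 50L, max_depth = 30L,
                  max_features = max(1L, floor(sqrt(ncol(x)))),
                  min_samples_leaf = 1L, seed = seed)
  imp <- sort(model$importance, decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             stringsAsFactors = FALSE)
}

#' @rdname rank_features
#' @param ranking result of [rank_features()].
#' @param max_k cap on the number of features (default 8).
#' @param cum_target cumulative importance target (default 0.95).
#' @return character vector of selected feature names.
#' @export
select_top_features <- function(ranking, max_k = 8L, cum_target = 0.95) {
  k <- which(cumsum(ranking$importance) >= cum_target)[1L]
  if (is.na(k)) k <- nrow(ranking)
  ranking$feature[seq_len(min(max_k, k))]
}

#' Macro-averaged F1 score
#'
#' Per-class F1 = 2PR/(P+R) (0 when P + R = 0), averaged over the reference
#' classes.
#' @param pred,ref label vectors.
#' @return macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(pred, ref) {
  classes <- unique(as.character(ref))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & ref == cl)
    p <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    r <- if (sum(ref == cl) > 0) tp / sum(ref == cl) else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Tune a classifier by cross-validated macro-F1
#'
#' Grid search over classifier parameters with stratified k-fold
#' cross-validation; the grid point maximizing mean macro-F1 wins, ties
#' going to the earlier grid row. The shipped default grids include the
#' parameter combinations adopted for the real-imagery study
#' (RF: depth 19, 8 features per split, 20 trees, leaf 2; KNN: k = 9,
#' uniform weights) but tuning may select differently on other data.
#'
#' @param kind `"rf"` or `"knn"`.
#' @param x,y training features and labels.
#' @param grid data.frame of parameter combinations; `NULL` = default grid.
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed.
#' @return a `classifier_spec`: list with `kind`, `params` (best row),
#'   `grid`, `cv_f1` per grid row, `features` used.
#' @export
tune_classifier <- function(kind = c("rf", "knn"), x, y, grid = NULL,
                            folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- factor_c_(y)
  stopifnot(folds >= 2L)
  if (min(table(y)) < folds) {
    stop("every class needs at least `folds` samples for stratified CV")
  }
  if (is.null(grid)) {
    grid <- if (kind == "rf") {
      expand.grid(max_depth = c(5L, 19L), max_features = c(3L, 8L),
                  n_estimators = c(20L), min_samples_leaf = c(2L, 5L))
    } else {
      data.frame(n_neighbors = c(3L, 5L, 9L, 15L))
    }
  }
  stopifnot(nrow(grid) >= 1L)
  fold_id <- with_seed_(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    id
  })
  cv_f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1 <- numeric(folds)
    for (fo in seq_len(folds)) {
      tr <- fold_id != fo
      pred <- if (kind == "rf") {
        m <- rf_fit(x[tr, , drop = FALSE], y[tr],
                    n_estimators = grid$n_estimators[g],
                    max_depth = grid$max_depth[g],
                    max_features = grid$max_features[g],
                    min_samples_leaf = grid$min_samples_leaf[g],
                    seed = seed + 7L * g + fo)
        rf_predict(m, x[!tr, , drop = FALSE])
      } else {
        knn_predict(x[tr, , drop = FALSE], x[!tr, , drop = FALSE], y[tr],
                    k = grid$n_neighbors[g])
      }
      f1[fo] <- macro_f1(as.character(pred), as.character(y[!tr]))
    }
    cv_f1[g] <- mean(f1)
  }
  best <- which.max(cv_f1) # ties -> first grid row
  structure(list(kind = kind, params = grid[best, , drop = FALSE],
                 grid = grid, cv_f1 = cv_f1, features = colnames(x),
                 seed = seed),
            class = "classifier_spec")
}

#' Train on the sample database and classify the whole scene
#'
#' Draws up to `target_n` (120) corrected samples per formation (pooled over
#' slopes, seeded), trains the requested classifier on the selected
#' features, and labels every vegetation object; objects classified
#' non-vegetation in layer 1 keep that label.
#'
#' @param spec a `classifier_spec` from [tune_classifier()] (or a list with
#'   `kind` and `params`).
#' @param sample_db a `sample_db` from [build_sample_db()].
#' @param features layer-2 feature table.
#' @param veg_labels character per object, `"vegetation"`/`"non-vegetation"`.
#' @param feature_names features to train on; default
#'   [clustering_features()] plus texture and dsm after ranking — pass
#'   explicitly for reproducibility.
#' @param target_n samples drawn per formation (default 120).
#' @param label_noise fraction of training labels randomly flipped (default
#'   0, used for robustness experiments).
#' @param seed integer seed.
#' @return list: `object_labels` (character per object), `model`,
#'   `training` (data.frame of object ids/classes used).
#' @export
train_classify <- function(spec, sample_db, features, veg_labels,
                           feature_names, target_n = 120L,
                           label_noise = 0, seed = 1L) {
  stopifnot(inherits(sample_db, "sample_db"))
  if (!any(veg_labels == "vegetation")) stop("empty vegetation mask")
  pool <- list()
  for (s in sample_db$sets) {
    pool[[length(pool) + 1L]] <- data.frame(object_id = s$ids,
                                            class = s$formation,
                                            stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, pool)
  training <- with_seed_(seed, {
    pool$class <- as.character(pool$class)
    cls_order <- sort(unique(pool$class), method = "radix")
    parts <- lapply(split(pool, factor(pool$class, levels = cls_order)),
                    function(d) {
      if (nrow(d) > target_n) d[sample.int(nrow(d), target_n), ] else d
    })
    do.call(rbind, parts)
  })
  rownames(training) <- NULL
  if (label_noise > 0) {
    training$class <- with_seed_(seed + 1L, {
      cl <- training$class
      flip <- runif(length(cl)) < label_noise
      classes <- unique(cl)
      cl[flip] <- vapply(cl[flip], function(c0) {
        sample(setdiff(classes, c0), 1L)
      }, character(1))
      cl
    })
  }
  rows <- match(training$object_id, features$object_id)
  x_train <- as.matrix(features[rows, feature_names])
  x_train[!is.finite(x_train)] <- 0
  y_train <- factor_c_(training$class)

  veg_rows <- which(veg_labels == "vegetation")
  x_all <- as.matrix(features[veg_rows, feature_names])
  x_all[!is.finite(x_all)] <- 0

  if (spec$kind == "rf") {
    model <- rf_fit(x_train, y_train,
                    n_estimators = spec$params$n_estimators,
                    max_depth = spec$params$max_depth,
                    max_features = spec$params$max_features,
                    min_samples_leaf = spec$params$min_samples_leaf,
                    seed = seed + 2L)
    pred <- rf_predict(model, x_all)
  } else {
    model <- list(kind = "knn", train = x_train, cl = y_train,
                  k = spec$params$n_neighbors)
    pred <- knn_predict(x_train, x_all, y_train, k = spec$params$n_neighbors)
  }
  labels <- veg_labels
  labels[labels == "non-vegetation"] <- "Non-vegetation"
  labels[veg_rows] <- as.character(pred)
  list(object_labels = labels, model = model, training = training)
}
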