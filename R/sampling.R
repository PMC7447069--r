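#' Candidate filter
#'
#' Screens out fragment polygons before clustering: objects must have at
#' least `min_area` pixels and a length/width ratio of at most
#' `max_length_width` (both inclusive).
#'
#' @param min_area pixels (>= 1); default 25.
#' @param max_length_width ratio (>= 1); default 5.
#' @return a `candidate_filter` list.
#' @export
candidate_filter <- function(min_area = 25, max_length_width = 5) {
  stopifnot(min_area >= 1, max_length_width >= 1)
  structure(list(min_area = min_area, max_length_width = max_length_width),
            class = "candidate_filter")
}

#' Filter belt candidates by area and length/width
#'
#' @param features a feature table from [compute_features()].
#' @param belt_members object ids belonging to the belt.
#' @param filter a [candidate_filter].
#' @return the retained object ids; an empty result warns (sparse belt) but
#'   is not an error.
#' @export
filter_candidates <- function(features, belt_members,
                              filter = candidate_filter()) {
  stopifnot(all(belt_members %in% features$object_id))
  rows <- match(belt_members, features$object_id)
  keep <- features$area[rows] >= filter$min_area &
    features$length_width[rows] <= filter$max_length_width
  out <- belt_members[keep]
  if (length(out) == 0L) {
    warning("no candidates survive the area/length-width filter")
  }
  out
}

#' Cluster belt candidates
#'
#' Clusters the candidate objects of a belt in the standardized clustering
#' feature space. Columns are z-scored internally (constant columns are
#' zeroed); `k` is honoured by the centroid-based algorithms and ignored by
#' DBSCAN and mean shift, which determine their own cluster count (eps from
#' the 4-NN distance knee; bandwidth from the median pairwise distance).
#'
#' @param features numeric matrix/data.frame of clustering features (rows =
#'   candidates).
#' @param k number of clusters (ignored by dbscan/meanshift).
#' @param algorithm one of `"kmeans"`, `"spectral"`, `"gaussian_mixture"`,
#'   `"agglomerative"`, `"dbscan"`, `"meanshift"`.
#' @param seed integer seed.
#' @return integer cluster labels (0 = DBSCAN noise).
#' @export
cluster_candidates <- function(features, k, algorithm = "kmeans",
                               seed = 1L) {
  algorithm <- match.arg(algorithm, c("kmeans", "spectral",
                                      "gaussian_mixture", "agglomerative",
                                      "dbscan", "meanshift"))
  x <- zscore_(as.matrix(features))
  needs_k <- !algorithm %in% c("dbscan", "meanshift")
  if (needs_k) {
    stopifnot(k >= 1L)
    if (k > nrow(x)) stop("k = ", k, " exceeds candidate count ", nrow(x))
    # identical objects (noiseless scenes) collapse to one point; k cannot
    # exceed the number of distinct rows
    k <- min(k, nrow(unique(x)))
    if (k == nrow(x)) return(seq_len(nrow(x)))
  }
  switch(algorithm,
         kmeans = kmeans_(x, k, seed),
         agglomerative = agglomerative_(x, k),
         gaussian_mixture = gaussian_mixture_(x, k, seed),
         spectral = spectral_(x, k, seed),
         dbscan = dbscan_(x),
         meanshift = meanshift_(x))
}

# prototype as a k x p matrix over the given feature columns; a prototype
# may carry several rows (mixed-forest classes: one per parent signature)
proto_matrix_ <- function(prototype, cols) {
  m <- if (is.null(dim(prototype))) {
    matrix(unlist(prototype)[cols], 1L, dimnames = list(NULL, cols))
  } else {
    as.matrix(as.data.frame(prototype)[, cols, drop = FALSE])
  }
  if (anyNA(m)) stop("prototype missing clustering features")
  m
}

# distance from a point to the nearest prototype row
proto_dist_ <- function(point, proto_rows) {
  min(sqrt(rowSums(sweep(proto_rows, 2, point)^2)))
}

zscore_ <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  sweep(sweep(x, 2, center), 2, scale, "/")
}

new_sample_set_ <- function(formation, slope, ids, stage, brightness,
                            audit = list()) {
  mu <- mean(brightness)
  sigma <- sqrt(mean((brightness - mu)^2)) # population sd (3-sigma rule)
  structure(list(formation = formation, slope = slope, ids = ids,
                 stage = stage, brightness = brightness, mu = mu,
                 sigma = sigma, audit = audit),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample set '%s' (%s slope): %d objects, stage %s\n",
              x$formation, x$slope, length(x$ids), x$stage))
  invisible(x)
}

#' Select the initial sample category from a clustering result
#'
#' Among the `top_m` clusters by member count, picks the cluster whose
#' standardized centroid lies nearest (Euclidean) to the formation prototype
#' — the automated version of comparing the top 3-5 categories with the
#' image and keeping the most suitable one. The full size/distance ranking
#' is kept in the audit trail.
#'
#' @param labels cluster labels from [cluster_candidates()] (0 = noise,
#'   excluded).
#' @param features the clustering feature matrix used for clustering (one
#'   row per candidate).
#' @param ids candidate object ids aligned with `labels`.
#' @param prototype named numeric vector (or one-row data.frame) of expected
#'   clustering-feature values for the formation.
#' @param top_m how many of the largest clusters to consider (default 5).
#' @param formation,slope metadata stored on the resulting set.
#' @param brightness per-candidate brightness (for the Pauta stage).
#' @return a `sample_set` with `stage = "initial"`.
#' @export
select_initial_category <- function(labels, features, ids, prototype,
                                    top_m = 5L, formation = "unknown",
                                    slope = "north", brightness = NULL) {
  keep <- labels > 0L
  if (!any(keep)) stop("clustering produced no clusters (all noise)")
  x <- as.matrix(features)
  if (is.null(brightness)) brightness <- x[, "brightness"]
  center <- colMeans(x[keep, , drop = FALSE])
  scale <- apply(x[keep, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- zscore_(x, center, scale)
  ps <- zscore_(proto_matrix_(prototype, colnames(x)), center, scale)

  sizes <- sort(table(labels[keep]), decreasing = TRUE)
  cand <- names(sizes)[seq_len(min(top_m, length(sizes)))]
  cents <- t(vapply(cand, function(cl) {
    colMeans(xs[labels == as.integer(cl), , drop = FALSE])
  }, numeric(ncol(xs))))
  cent_dist <- apply(cents, 1, proto_dist_, proto_rows = ps)
  # one winning cluster per prototype row: mixed-forest classes carry a
  # prototype per parent signature and their sample base must cover both
  # spectral modes of the stand
  best <- unique(vapply(seq_len(nrow(ps)), function(r) {
    d <- sqrt(rowSums(sweep(cents, 2, ps[r, ])^2))
    cand[which.min(d)]
  }, character(1)))
  ranking <- data.frame(cluster = as.integer(cand),
                        size = as.integer(sizes[cand]),
                        prototype_distance = as.numeric(cent_dist))
  sel <- labels %in% as.integer(best)
  new_sample_set_(formation, slope, ids[sel], "initial", brightness[sel],
                  audit = list(ranking = ranking,
                               selected_cluster = as.integer(best)))
}

#' Purify a sample set with the Pauta (3-sigma) criterion
#'
#' Retains exactly the objects whose brightness lies within three standard
#' deviations of the set mean: `|x_i - mu| <= 3 sigma`, with `mu`, `sigma`
#' the mean and (population) standard deviation of brightness over the input
#' set. `sigma = 0` retains everything; sets with fewer than 2 members are
#' returned unchanged with a warning.
#'
#' @param samples a `sample_set` with `stage = "initial"`.
#' @return a `sample_set` with `stage = "purified"`.
#' @export
pauta_purify <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  n <- length(samples$ids)
  if (n < 2L) {
    warning("fewer than 2 samples; Pauta purification skipped")
    samples$stage <- "purified"
    return(samples)
  }
  keep <- if (samples$sigma == 0) rep(TRUE, n) else
    abs(samples$brightness - samples$mu) <= 3 * samples$sigma
  out <- new_sample_set_(samples$formation, samples$slope,
                         samples$ids[keep], "purified",
                         samples$brightness[keep], samples$audit)
  out$audit$pauta_removed <- sum(!keep)
  out
}

#' Correct a sample set by iterative 2-clustering
#'
#' Repeatedly 2-means the set in standardized clustering-feature space and
#' keeps the cluster whose centroid is nearer the formation prototype,
#' stripping contaminating classes. Stops when (a) the standardized
#' inter-centroid distance falls below `balance_tol` (the two categories are
#' "roughly the same"), (b) the kept size reaches `target_n` (close to 120),
#' or (c) `max_iter` is hit. Fails if fewer than `min_keep` samples survive.
#'
#' @param samples a `sample_set` with `stage = "purified"`.
#' @param features clustering feature matrix for **all** objects, indexed by
#'   the rownames/`ids` mapping in `ids_all`.
#' @param ids_all object ids aligned with the rows of `features`.
#' @param prototype expected clustering-feature vector of the formation.
#' @param params a [sampling_params].
#' @param seed integer seed.
#' @return a `sample_set` with `stage = "corrected"` and an iteration log in
#'   `$audit$correction_log`.
#' @export
iterative_correct <- function(samples, features, ids_all, prototype,
                              params = sampling_params(), seed = 1L) {
  stopifnot(inherits(samples, "sample_set"))
  x_all <- as.matrix(features)
  pm <- proto_matrix_(prototype, colnames(x_all))
  ids <- samples$ids
  # standardization is frozen on the entry set: re-scaling inside the loop
  # would inflate distances as the surviving set grows homogeneous
  rows0 <- match(ids, ids_all)
  center <- colMeans(x_all[rows0, , drop = FALSE])
  scale <- apply(x_all[rows0, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  log <- list()
  iter <- 0L
  while (iter < params$max_iter && length(ids) >= 4L) {
    iter <- iter + 1L
    rows <- match(ids, ids_all)
    xs <- zscore_(x_all[rows, , drop = FALSE], center, scale)
    if (nrow(unique(xs)) < 2L) {
      # perfectly homogeneous set (noiseless limit): nothing to correct
      log[[iter]] <- data.frame(iter = iter, n_before = length(ids),
                                n_after = length(ids), separation = 0,
                                action = "stop: homogeneous")
      break
    }
    cl <- with_seed_(seed + iter, stats::kmeans(xs, centers = 2L,
                                                nstart = 10L,
                                                iter.max = 100L))
    ps <- zscore_(pm, center, scale)
    dists <- apply(cl$centers, 1, proto_dist_, proto_rows = ps)
    # "accuracy degree roughly the same": both centroids about equally near
    # the prototype (2-means always separates standardized homogeneous data,
    # so raw inter-centroid distance cannot serve as the balance test)
    sep <- abs(dists[1L] - dists[2L])
    if (sep < params$balance_tol) {
      log[[iter]] <- data.frame(iter = iter, n_before = length(ids),
                                n_after = length(ids), separation = sep,
                                action = "stop: balanced")
      break
    }
    keep_cl <- which.min(dists)
    kept <- ids[cl$cluster == keep_cl]
    if (length(kept) < params$min_keep) {
      # refuse a correction that would destroy the sample base
      log[[iter]] <- data.frame(iter = iter, n_before = length(ids),
                                n_after = length(ids), separation = sep,
                                action = "stop: keep would fall below min_keep")
      break
    }
    log[[iter]] <- data.frame(iter = iter, n_before = length(ids),
                              n_after = length(kept), separation = sep,
                              action = "keep nearer-to-prototype cluster")
    ids <- kept
    if (length(ids) <= params$target_n) break
  }
  if (length(ids) < params$min_keep) {
    stop("iterative correction left ", length(ids), " < min_keep = ",
         params$min_keep, " samples for ", samples$formation)
  }
  rows <- match(ids, ids_all)
  out <- new_sample_set_(samples$formation, samples$slope, ids, "corrected",
                         x_all[rows, "brightness"], samples$audit)
  out$audit$correction_log <- if (length(log)) do.call(rbind, log) else
    data.frame(iter = integer(), n_before = integer(), n_after = integer(),
               separation = numeric(), action = character())
  out
}

#' Build the per-formation sample databases for a scene
#'
#' Runs the full automatic selection for every belt of both slopes: belt
#' candidates (vegetation objects only) are filtered, clustered with
#' `k = k_multiplier x` (number of formations near the belt), the initial
#' category is chosen against the formation prototype, Pauta-purified and
#' iteratively corrected. The Basal-zone stratum is sampled as "Cultivated
#' plants". Formations that fail (too few survivors) are recorded in the
#' report and skipped, not fatal.
#'
#' @param features feature table from [compute_features()].
#' @param belt_assign per-object belt ids from [assign_objects()].
#' @param table a [mab_table].
#' @param prototypes prototype table ([prototypes_from_signatures()]).
#' @param veg_object logical per object: is it vegetation (layer-1 result)?
#'   `NULL` = all objects.
#' @param params a [sampling_params].
#' @param filter a [candidate_filter].
#' @param algorithm clustering algorithm for the initial selection.
#' @param seed integer seed.
#' @return A `sample_db`: list with `sets` (named list of corrected
#'   `sample_set`s, names `"<slope>:<formation>"`) and `report` (data.frame
#'   of per-belt outcomes).
#' @export
build_sample_db <- function(features, belt_assign, table = load_mab_table(),
                            prototypes = prototypes_from_signatures(),
                            veg_object = NULL,
                            params = sampling_params(),
                            filter = candidate_filter(),
                            algorithm = "kmeans", seed = 1L) {
  if (is.null(veg_object)) veg_object <- rep(TRUE, nrow(features))
  feats <- clustering_features()
  sets <- list()
  report <- NULL
  for (bi in seq_len(nrow(table))) {
    belt <- table[bi, ]
    target <- if (is_basal_(belt$formation)) "Cultivated plants" else
      belt$formation
    members <- features$object_id[!is.na(belt_assign) &
                                    belt_assign == belt$belt_id & veg_object]
    status <- "ok"
    n_corr <- NA_integer_
    set <- NULL
    res <- tryCatch({
      cand <- suppressWarnings(
        filter_candidates(features, members, filter))
      if (length(cand) < params$min_keep) stop("too few candidates (",
                                               length(cand), ")")
      k <- if (is_basal_(belt$formation)) params$k_multiplier else
        cluster_count(length(formations_near(table, belt$slope, belt$alt_lo,
                                             belt$alt_hi,
                                             params$near_delta)), params)
      k <- min(k, length(cand))
      rows <- match(cand, features$object_id)
      x <- as.matrix(features[rows, feats])
      x[!is.finite(x)] <- 0
      labels <- cluster_candidates(x, k, algorithm, seed = seed + bi)
      proto <- prototypes[prototypes$class == target, feats]
      if (nrow(proto) < 1L) stop("no prototype for ", target)
      init <- select_initial_category(labels, x, cand, proto,
                                      top_m = params$top_m,
                                      formation = target,
                                      slope = belt$slope)
      pur <- pauta_purify(init)
      x_all <- as.matrix(features[, feats])
      x_all[!is.finite(x_all)] <- 0
      corr <- iterative_correct(pur, x_all, features$object_id, proto,
                                params, seed = seed + 1000L + bi)
      corr$audit$initial_ids <- init$ids
      corr$audit$purified_ids <- pur$ids
      corr$audit$candidate_ids <- cand
      corr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- conditionMessage(res)
    } else {
      set <- res
      n_corr <- length(set$ids)
      sets[[paste0(belt$slope, ":", target)]] <- set
    }
    report <- rbind(report, data.frame(
      slope = belt$slope, formation = target, belt_id = belt$belt_id,
      n_members = length(members), n_corrected = n_corr, status = status,
      stringsAsFactors = FALSE))
  }
  structure(list(sets = sets, report = report), class = "sample_db")
}

#' Compare clustering algorithms on first-pass sample accuracy
#'
#' Runs the initial category selection with each algorithm on every belt of
#' the scene and scores the selected samples against the ground truth,
#' averaged over seeds. Mirrors the published comparison table: one column
#' per algorithm, one row per formation stratum, plus a final `Mean` row
#' (arithmetic mean over the available entries of each column).
#'
#' @param features,belt_assign,table,prototypes,veg_object,params,filter see
#'   [build_sample_db()].
#' @param truth_labels per-object majority truth class name (character).
#' @param algorithms algorithms to compare.
#' @param seeds integer vector of seeds to average over.
#' @return data.frame: `formation` column, one column per algorithm (NA
#'   where an algorithm failed on a belt) and a final `Mean` row.
#' @export
compare_algorithms <- function(features, belt_assign, truth_labels,
                               table = load_mab_table(),
                               prototypes = prototypes_from_signatures(),
                               veg_object = NULL,
                               params = sampling_params(),
                               filter = candidate_filter(),
                               algorithms = c("kmeans", "spectral",
                                              "gaussian_mixture",
                                              "agglomerative", "dbscan",
                                              "meanshift"),
                               seeds = 1L) {
  if (is.null(veg_object)) veg_object <- rep(TRUE, nrow(features))
  feats <- clustering_features()
  strata <- table[!is_basal_(table$formation), , drop = FALSE]
  acc <- array(NA_real_, c(nrow(strata), length(algorithms), length(seeds)))
  for (si in seq_along(seeds)) {
    for (bi in seq_len(nrow(strata))) {
      belt <- strata[bi, ]
      members <- features$object_id[!is.na(belt_assign) &
                                      belt_assign == belt$belt_id &
                                      veg_object]
      cand <- suppressWarnings(filter_candidates(features, members, filter))
      if (length(cand) < 3L) next
      k <- min(cluster_count(length(formations_near(
        table, belt$slope, belt$alt_lo, belt$alt_hi, params$near_delta)),
        params), length(cand))
      rows <- match(cand, features$object_id)
      x <- as.matrix(features[rows, feats])
      x[!is.finite(x)] <- 0
      proto <- prototypes[prototypes$class == belt$formation, feats]
      for (ai in seq_along(algorithms)) {
        res <- tryCatch({
          labels <- cluster_candidates(x, k, algorithms[ai],
                                       seed = seeds[si] + bi)
          set <- select_initial_category(labels, x, cand, proto,
                                         top_m = params$top_m,
                                         formation = belt$formation,
                                         slope = belt$slope)
          mean(truth_labels[match(set$ids, features$object_id)] ==
                 belt$formation, na.rm = TRUE)
        }, error = function(e) NA_real_)
        acc[bi, ai, si] <- res
      }
    }
  }
  m <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  out <- data.frame(formation = paste0(strata$slope, ":", strata$formation),
                    stringsAsFactors = FALSE)
  for (ai in seq_along(algorithms)) out[[algorithms[ai]]] <- m[, ai]
  means <- vapply(algorithms, function(a) mean(out[[a]], na.rm = TRUE),
                  numeric(1))
  out <- rbind(out, c(formation = "Mean", as.list(means)))
  out
}
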