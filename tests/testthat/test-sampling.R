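test_that("filter_candidates applies inclusive thresholds", {
  f <- data.frame(object_id = 1:4, area = c(24, 25, 100, 100),
                  length_width = c(2, 2, 5, 5.1))
  flt <- candidate_filter(min_area = 25, max_length_width = 5)
  expect_equal(filter_candidates(f, 1:4, flt), c(2L, 3L))
  expect_equal(filter_candidates(f, 1:4, candidate_filter(1, Inf)), 1:4)
  expect_warning(out <- filter_candidates(f, 1L, flt), "no candidates")
  expect_length(out, 0)
  expect_error(candidate_filter(min_area = 0))
})

blob_fixture <- function(n_per = 30, sep = 10, p = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p, mean = sep), n_per))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, truth = rep(1:2, each = n_per))
  })
}

test_that("all six clustering algorithms separate 10-sigma blobs", {
  fx <- blob_fixture()
  for (alg in c("kmeans", "spectral", "gaussian_mixture", "agglomerative",
                "dbscan", "meanshift")) {
    lab <- cluster_candidates(fx$x, 2L, alg, seed = 1)
    core <- lab > 0 # dbscan may mark noise
    expect_gt(mean(core), 0.9)
    tab <- table(lab[core], fx$truth[core])
    # each cluster maps to exactly one blob
    purity <- sum(apply(tab, 1, max)) / sum(tab)
    expect_equal(purity, 1.0)
  }
})

test_that("kmeans labels agree with a brute-force nearest-centroid check", {
  fx <- blob_fixture()
  lab <- cluster_candidates(fx$x, 2L, "kmeans", seed = 3)
  xs <- scale(fx$x)
  cents <- rbind(colMeans(xs[lab == 1, ]), colMeans(xs[lab == 2, ]))
  nearest <- apply(xs, 1, function(v) {
    which.min(c(sum((v - cents[1, ])^2), sum((v - cents[2, ])^2)))
  })
  expect_equal(as.integer(lab), as.integer(nearest))
})

test_that("cluster_candidates: degenerate k and determinism", {
  fx <- blob_fixture()
  expect_true(all(cluster_candidates(fx$x, 1L, "kmeans", seed = 1) == 1L))
  expect_error(cluster_candidates(fx$x, 1000L, "kmeans", seed = 1),
               "exceeds")
  expect_identical(cluster_candidates(fx$x, 3L, "kmeans", seed = 9),
                   cluster_candidates(fx$x, 3L, "kmeans", seed = 9))
  # duplicate rows cap the effective k instead of erroring
  xdup <- fx$x[rep(1:3, each = 10), ]
  expect_silent(cluster_candidates(xdup, 5L, "kmeans", seed = 1))
})

proto_fixture <- function() {
  # cluster 1: 40 points far from prototype; cluster 2: 20 points at it
  withr::with_seed(11, {
    p <- 4
    far <- matrix(rnorm(40 * p, mean = 8, sd = 0.5), 40)
    near <- matrix(rnorm(20 * p, mean = 0, sd = 0.5), 20)
    x <- rbind(far, near)
    colnames(x) <- c("brightness", "a", "b", "c")
    proto <- c(brightness = 0, a = 0, b = 0, c = 0)
    list(x = x, labels = rep(c(1L, 2L), c(40, 20)), proto = proto)
  })
}

test_that("select_initial_category prefers suitability over size", {
  fx <- proto_fixture()
  set <- select_initial_category(fx$labels, fx$x, ids = seq_len(60),
                                 prototype = fx$proto, top_m = 5,
                                 formation = "f", slope = "north")
  expect_equal(sort(set$ids), 41:60) # the on-prototype minority cluster
  expect_equal(set$stage, "initial")
  expect_equal(nrow(set$audit$ranking), 2L)
  # top_m = 1 degenerates to the largest cluster
  set1 <- select_initial_category(fx$labels, fx$x, ids = seq_len(60),
                                  prototype = fx$proto, top_m = 1,
                                  formation = "f", slope = "north")
  expect_equal(sort(set1$ids), 1:40)
})

test_that("pauta_purify implements the 3-sigma rule with population sd", {
  s <- make_sample_set("f", 1:4, c(10, 10, 10, 10))
  expect_equal(length(pauta_purify(s)$ids), 4L) # sigma = 0 retains all
  # {0 x 9, 100}: mu = 10, population sigma = 30, |100 - 10| = 3 sigma
  s2 <- make_sample_set("f", 1:10, c(rep(0, 9), 100))
  expect_equal(s2$mu, 10)
  expect_equal(s2$sigma, 30)
  p2 <- pauta_purify(s2)
  expect_equal(length(p2$ids), 10L)
  expect_equal(p2$stage, "purified")
  # a genuine outlier is removed
  s3 <- make_sample_set("f", 1:11, c(rnorm(10, 100, 1), 500))
  expect_false(11L %in% pauta_purify(s3)$ids)
  expect_warning(pauta_purify(make_sample_set("f", 1L, 5)), "fewer than 2")
})

test_that("pauta_purify retains ~99.7% of standard-normal draws", {
  withr::with_seed(8, {
    kept <- mean(vapply(1:5, function(i) {
      s <- make_sample_set("f", seq_len(10000), rnorm(10000))
      length(pauta_purify(s)$ids) / 10000
    }, numeric(1)))
  })
  expect_lt(abs(kept - 0.997), 0.002)
})

test_that("a second Pauta pass removes no more than the first", {
  withr::with_seed(13, {
    for (i in 1:10) {
      b <- rnorm(200, sd = sample(c(1, 10), 1)) + rt(200, df = 3)
      s <- make_sample_set("f", seq_len(200), b)
      p1 <- pauta_purify(s)
      removed1 <- 200 - length(p1$ids)
      p2 <- pauta_purify(make_sample_set("f", p1$ids, p1$brightness))
      removed2 <- length(p1$ids) - length(p2$ids)
      expect_lte(removed2, removed1 + 1e-9)
    }
  })
})

test_that("iterative_correct strips a 10-sigma contaminant in one pass", {
  withr::with_seed(17, {
    p <- length(clustering_features())
    good <- matrix(rnorm(150 * p, 0, 1), 150)
    bad <- matrix(rnorm(50 * p, 10, 1), 50)
    x <- rbind(good, bad)
    colnames(x) <- clustering_features()
    proto <- setNames(rep(0, p), clustering_features())
    s <- make_sample_set("f", seq_len(200), x[, "brightness"],
                         stage = "purified")
    out <- iterative_correct(s, x, seq_len(200), proto,
                             sampling_params(), seed = 5)
    expect_equal(out$stage, "corrected")
    expect_equal(sort(out$ids), 1:150)
    expect_equal(out$audit$correction_log$iter[1], 1L)
  })
})

test_that("iterative_correct never grows the set and terminates", {
  withr::with_seed(19, {
    p <- length(clustering_features())
    x <- matrix(rnorm(80 * p), 80)
    colnames(x) <- clustering_features()
    proto <- setNames(rep(0, p), clustering_features())
    s <- make_sample_set("f", seq_len(80), x[, "brightness"],
                         stage = "purified")
    out <- iterative_correct(s, x, seq_len(80), proto,
                             sampling_params(max_iter = 4), seed = 2)
    expect_lte(length(out$ids), 80L)
    expect_lte(nrow(out$audit$correction_log), 4L)
    expect_true(all(out$ids %in% s$ids))
    # homogeneous + identical points: returned unchanged
    xh <- matrix(1, 30, p)
    colnames(xh) <- clustering_features()
    sh <- make_sample_set("f", seq_len(30), xh[, "brightness"],
                          stage = "purified")
    oh <- iterative_correct(sh, xh, seq_len(30), proto, seed = 1)
    expect_equal(length(oh$ids), 30L)
    # a set collapsing below min_keep errors
    expect_error(iterative_correct(
      make_sample_set("f", 1:3, c(1, 2, 3), stage = "purified"),
      x[1:3, ], 1:3, proto, sampling_params(min_keep = 10)), "min_keep")
  })
})

test_that("build_sample_db: subset chain, naming, determinism", {
  run <- small_scene_run()
  db <- suppressWarnings(build_sample_db(
    run$features, run$belt_assign, run$scene$table,
    prototypes_from_signatures(), filter = candidate_filter(min_area = 5),
    seed = 11))
  expect_s3_class(db, "sample_db")
  expect_equal(nrow(db$report), nrow(run$scene$table))
  # Quercus liaotungensis only on the north slope
  qn <- grep("liaotungensis", names(db$sets), value = TRUE)
  expect_true(all(startsWith(qn, "north:")))
  # subset chain: corrected <= purified <= initial <= candidates
  for (nm in names(db$sets)) {
    s <- db$sets[[nm]]
    expect_true(all(s$ids %in% s$audit$purified_ids))
    expect_true(all(s$audit$purified_ids %in% s$audit$initial_ids))
    expect_true(all(s$audit$initial_ids %in% s$audit$candidate_ids))
  }
  db2 <- suppressWarnings(build_sample_db(
    run$features, run$belt_assign, run$scene$table,
    prototypes_from_signatures(), filter = candidate_filter(min_area = 5),
    seed = 11))
  expect_identical(lapply(db$sets, `[[`, "ids"),
                   lapply(db2$sets, `[[`, "ids"))
})

test_that("compare_algorithms reports per-formation columns plus a Mean row", {
  run <- small_scene_run()
  res <- suppressWarnings(compare_algorithms(
    run$features, run$belt_assign, run$truth_class, run$scene$table,
    prototypes_from_signatures(),
    filter = candidate_filter(min_area = 5),
    algorithms = c("kmeans", "agglomerative"), seeds = 1L))
  expect_equal(names(res), c("formation", "kmeans", "agglomerative"))
  expect_equal(res$formation[nrow(res)], "Mean")
  body <- res[-nrow(res), ]
  for (alg in c("kmeans", "agglomerative")) {
    vals <- as.numeric(body[[alg]])
    expect_equal(as.numeric(res[[alg]][nrow(res)]),
                 mean(vals, na.rm = TRUE))
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  }
})

test_that("corrected-sample purity degrades monotonically with noise (property)", {
  # rank correlation between noise level and mean corrected purity < 0,
  # measured on small scenes over a fixed seed grid
  purity_at <- function(sd_scale, bsig, seed) {
    sc <- synth_scene(rows = 192L, cols = 64L, sd_scale = sd_scale,
                      boundary_sigma = bsig, seed = seed)
    l2 <- segment(scene_stack(sc),
                  segmentation_params(scale = 10,
                                      band_weights = c(1, 1, 1, 2, 0.05)))
    f2 <- compute_features(l2, sc$image, sc$dsm)
    belts <- build_constraint_raster(sc$dsm, split_slopes(sc$dsm), sc$table)
    ba <- assign_objects(l2, belts)
    db <- suppressWarnings(build_sample_db(
      f2, ba, sc$table, prototypes_from_signatures(),
      filter = candidate_filter(min_area = 5), seed = seed + 1))
    tc <- sc$legend$class[vegbelt:::majority_labels_(l2, sc$truth)]
    mean(vapply(db$sets, function(s) {
      sample_accuracy(s, tc, f2$object_id)
    }, numeric(1)), na.rm = TRUE)
  }
  levels <- list(c(0.5, 20), c(2, 80), c(4, 160))
  seeds <- 1:4
  mp <- vapply(levels, function(lv) {
    mean(vapply(seeds, function(s) purity_at(lv[1], lv[2], s), numeric(1)))
  }, numeric(1))
  expect_lt(cor(seq_along(mp), mp, method = "spearman"), 0)
})
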