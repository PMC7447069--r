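test_that("degenerate scales behave as specified", {
  u <- matrix(5, 6, 6)
  # zero colour heterogeneity: one object at any positive scale when the
  # cost is colour-only (shape heterogeneity of a growing region is > 0)
  p0 <- segmentation_params(scale = 1, shape_factor = 0, band_weights = 1)
  expect_equal(segment(u, p0)$n_objects, 1L)
  # scale 0: no merges at all
  expect_equal(segment(u, segmentation_params(scale = 0, shape_factor = 0,
                                              band_weights = 1))$n_objects,
               36L)
  expect_error(segment(matrix(numeric(0), 0, 0), p0), "empty")
})

test_that("two-halves image yields exactly 2 objects between the costs", {
  # 4x4, halves 0 | 100: the only positive costs are cross-half merges; the
  # final cross merge costs n_m * sd_m = 16 * 50 = 800, so any scale with
  # 0 < scale^2 < 800 stops at the two halves
  img <- matrix(c(rep(0, 8), rep(100, 8)), 4, 4)
  p <- segmentation_params(scale = 20, shape_factor = 0, band_weights = 1)
  om <- segment(img, p)
  expect_equal(om$n_objects, 2L)
  expect_equal(length(unique(as.integer(om$labels[, 1:2]))), 1L)
  expect_equal(length(unique(as.integer(om$labels[, 3:4]))), 1L)
  # above the cross-half cost everything merges
  p2 <- segmentation_params(scale = 29, shape_factor = 0, band_weights = 1)
  expect_equal(segment(img, p2)$n_objects, 1L)
})

test_that("segment output is a partition with contiguous ids", {
  sc <- synth_scene(rows = 48, cols = 32, seed = 3)
  om <- segment(scene_stack(sc),
                segmentation_params(scale = 10,
                                    band_weights = c(1, 1, 1, 2, 0.05)))
  expect_false(anyNA(om$labels))
  expect_equal(sort(unique(as.integer(om$labels))), seq_len(om$n_objects))
})

test_that("object count is monotone non-increasing in scale (property)", {
  withr::with_seed(21, img <- matrix(sample(0:3, 100, TRUE), 10, 10))
  counts <- vapply(c(0, 1, 2, 4, 8, 16, 32), function(s) {
    segment(img, segmentation_params(scale = s, shape_factor = 0.2,
                                     compactness = 0.6,
                                     band_weights = 1))$n_objects
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment matches the brute-force oracle on random small images", {
  withr::with_seed(77, {
    for (i in 1:10) {
      img <- matrix(sample(c(0, 100), 16, TRUE), 4, 4)
      for (s in c(5, 15, 40)) {
        impl <- segment(img, segmentation_params(scale = s,
                                                 shape_factor = 0.2,
                                                 compactness = 0.6,
                                                 band_weights = 1))$labels
        expect_identical(impl, brute_segment(img, s, shape_factor = 0.2,
                                             compactness = 0.6))
      }
    }
  })
})

test_that("mean-variance curve: constant image is 0, peak marks the split", {
  u <- matrix(7, 5, 5)
  cur <- mean_variance_curve(u, segmentation_params(shape_factor = 0,
                                                    band_weights = 1),
                             scales = c(1, 5, 10))
  expect_equal(nrow(cur), 3L)
  expect_equal(cur$mean_variance, rep(0, 3))
  img <- matrix(c(rep(0, 8), rep(100, 8)), 4, 4)
  cur2 <- mean_variance_curve(list(nir = img),
                              segmentation_params(shape_factor = 0,
                                                  band_weights = 1),
                              scales = c(1, 20, 40))
  # the scale first yielding the 2 pure halves attains the maximum (50^2);
  # degenerate finer scales tie with it on this noiseless toy image
  expect_equal(cur2$mean_variance[2], 2500)
  expect_equal(max(cur2$mean_variance), cur2$mean_variance[2])
})

test_that("select_scale picks the peak with small-scale tie-breaking", {
  expect_equal(select_scale(data.frame(scale = c(100, 140, 200),
                                       v = c(1, 5, 2))), 140)
  # the tie winner is also an endpoint here, so the boundary warning fires
  expect_equal(suppressWarnings(select_scale(data.frame(scale = c(100, 140),
                                                        v = c(3, 3)))), 100)
  expect_warning(sel <- select_scale(data.frame(scale = c(100, 140, 180),
                                                v = c(1, 2, 3))),
                 "boundary")
  expect_equal(sel, 180)
  expect_error(select_scale(data.frame()), "empty")
})

test_that("compute_features reproduces hand-computed values", {
  # one object with constant band values (40, 50, 60, 120)
  img <- array(0, c(3, 3, 4), dimnames = list(NULL, NULL,
                                              c("blue", "green", "red",
                                                "nir")))
  img[, , 1] <- 40; img[, , 2] <- 50; img[, , 3] <- 60; img[, , 4] <- 120
  om <- structure(list(labels = matrix(1L, 3, 3), n_objects = 1L,
                       params = segmentation_params()),
                  class = "object_map")
  f <- compute_features(om, img, matrix(1500, 3, 3))
  expect_equal(f$brightness, 67.5)
  expect_equal(f$dvi, 60)
  expect_equal(f$ndvi, 1 / 3)
  expect_equal(f$rvi, 2)
  expect_equal(f$max_diff, 80 / 67.5)
  expect_equal(f$area, 9)
  expect_equal(f$dsm_mean, 1500)
  # constant object: zero texture
  expect_equal(f$glcm_contrast, 0)
  expect_equal(f$glcm_entropy, 0)
  # square object: unit aspect ratio
  expect_equal(f$length_width, 1)
})

test_that("NIR = Red gives the identity index values; Red = 0 is flagged", {
  img <- array(80, c(2, 2, 4), dimnames = list(NULL, NULL,
                                               c("blue", "green", "red",
                                                 "nir")))
  om <- structure(list(labels = matrix(1L, 2, 2), n_objects = 1L),
                  class = "object_map")
  f <- compute_features(om, img, matrix(0, 2, 2))
  expect_equal(f$ndvi, 0)
  expect_equal(f$dvi, 0)
  expect_equal(f$rvi, 1)
  img[, , "red"] <- 0
  f2 <- compute_features(om, img, matrix(0, 2, 2))
  expect_true(is.na(f2$rvi))
  expect_false(f2$rvi_defined)
})

test_that("features are invariant to object id relabelling", {
  sc <- synth_scene(rows = 32, cols = 32, seed = 5)
  om <- segment(scene_stack(sc),
                segmentation_params(scale = 10,
                                    band_weights = c(1, 1, 1, 2, 0.05)))
  f1 <- compute_features(om, sc$image, sc$dsm)
  perm <- rev(seq_len(om$n_objects))
  om2 <- structure(list(labels = matrix(perm[om$labels], nrow(om$labels)),
                        n_objects = om$n_objects), class = "object_map")
  f2 <- compute_features(om2, sc$image, sc$dsm)
  reordered <- f2[match(perm, f2$object_id), ]
  rownames(reordered) <- NULL
  expect_equal(reordered[, -1], f1[, -1], tolerance = 1e-12)
})
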