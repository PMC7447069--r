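rf_fixture <- function() {
  read_confusion_csv(system.file("extdata", "confusion_rf.csv",
                                 package = "vegbelt"))
}

test_that("confusion builds predicted-by-reference counts", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(unname(cm["a", "a"]), 1L)
  expect_equal(unname(cm["a", "b"]), 1L)
  expect_equal(unname(cm["b", "b"]), 1L)
  expect_equal(sum(cm), 3L)
  # identical sequences give a diagonal matrix
  cm2 <- confusion(letters[1:4], letters[1:4])
  expect_equal(sum(diag(cm2)), 4L)
  expect_equal(sum(cm2) - sum(diag(cm2)), 0L)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion("a", "z", classes = c("a", "b")), "outside")
  expect_error(confusion(c("a", "a"), "a"), "lengths differ")
})

test_that("published RF matrix reproduces its printed marginals", {
  cm <- rf_fixture()
  expect_equal(unname(rowSums(cm)),
               c(220, 179, 100, 66, 96, 118, 124, 49, 18, 26, 4))
  expect_equal(sum(cm), 1000L)
})

test_that("confusion is permutation-equivariant in the class order", {
  withr::with_seed(3, {
    pred <- sample(letters[1:4], 60, TRUE)
    ref <- sample(letters[1:4], 60, TRUE)
    cm <- confusion(pred, ref, letters[1:4])
    perm <- c("c", "a", "d", "b")
    cm2 <- confusion(pred, ref, perm)
    expect_equal(unclass(cm2), unclass(cm)[perm, perm])
    expect_equal(kappa(cm2), kappa(cm))
    expect_equal(overall_accuracy(cm2), overall_accuracy(cm))
  })
})

test_that("kappa identities: independence gives 0, perfection gives 1", {
  ind <- as_confusion(matrix(c(9, 1, 81, 9), 2, 2), c("a", "b"))
  expect_equal(kappa(ind), 0)
  perf <- as_confusion(diag(c(5L, 7L)), c("a", "b"))
  expect_equal(kappa(perf), 1)
  expect_equal(overall_accuracy(perf), 1)
  one <- as_confusion(matrix(10L, 1, 1), "a")
  expect_equal(kappa(one), 1) # p_e = 1 with p_o = 1
})

test_that("kappa < observed agreement whenever chance agreement > 0", {
  withr::with_seed(9, {
    for (i in 1:20) {
      m <- matrix(rpois(16, 5), 4, 4)
      diag(m) <- diag(m) + rpois(4, 10)
      cm <- as_confusion(m, letters[1:4])
      po <- overall_accuracy(cm)
      if (po < 1) expect_lt(kappa(cm), po)
    }
  })
})

test_that("user/producer accuracy flag empty denominators", {
  m <- as_confusion(matrix(c(5L, 0L, 3L, 0L), 2, 2), c("a", "b"))
  expect_equal(unname(user_accuracy(m, "a")), 5 / 8)
  expect_true(is.na(user_accuracy(m, "b")))
  expect_true(attr(user_accuracy(m, "b"), "undefined"))
  expect_equal(unname(producer_accuracy(m, "a")), 1)
  expect_error(user_accuracy(m, "zzz"), "unknown class")
})

test_that("sample accuracy: fractions and the regional weighted identity", {
  run <- small_scene_run()
  s <- make_sample_set("Quercus variabilis forest",
                       run$features$object_id[1:4], rep(1, 4))
  tc <- rep("x", nrow(run$features))
  tc[1:3] <- "Quercus variabilis forest"
  expect_equal(sample_accuracy(s, tc, run$features$object_id), 0.75)
  expect_error(sample_accuracy(make_sample_set("f", integer(0), numeric(0)),
                               tc, run$features$object_id), "empty")
  # full report: per-set accuracy recombines regional means by weight
  db <- suppressWarnings(build_sample_db(
    run$features, run$belt_assign, run$scene$table,
    prototypes_from_signatures(), filter = candidate_filter(min_area = 5),
    seed = 11))
  rep_ <- sample_accuracy_report(db, run$truth_class, run$features,
                                 run$objects)
  summ <- attr(rep_, "summary")
  expect_equal(summ$overall,
               sum(rep_$accuracy * rep_$n) / sum(rep_$n))
  expect_true(all(c("west", "middle", "east") %in% names(rep_)))
  expect_true(all(names(summ$by_slope) %in% c("north", "south")))
})

test_that("validation_points: determinism and the binomial error count", {
  withr::with_seed(12, {
    ref <- matrix(sample(letters[1:3], 400, TRUE), 20, 20)
    pred <- ref
    flip <- sample(400, 80) # OA = 0.8
    pred[flip] <- ifelse(pred[flip] == "a", "b", "a")
    vp1 <- validation_points(pred, ref, n = 200, seed = 5)
    vp2 <- validation_points(pred, ref, n = 200, seed = 5)
    expect_identical(vp1$error_points, vp2$error_points)
    # pred == ref gives zero error points
    vp0 <- validation_points(ref, ref, n = 100, seed = 1)
    expect_equal(nrow(vp0$error_points), 0L)
    expect_equal(overall_accuracy(vp0$confusion), 1)
    # error count concentrates near n * (1 - OA)
    oa <- mean(pred == ref)
    errs <- vapply(1:20, function(s) {
      nrow(validation_points(pred, ref, n = 200, seed = s)$error_points)
    }, numeric(1))
    expect_lt(abs(mean(errs) - 200 * (1 - oa)), 3 * sqrt(200 * 0.2 * 0.8))
    expect_error(validation_points(pred, ref, n = 1e6), "fewer than n")
  })
})
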