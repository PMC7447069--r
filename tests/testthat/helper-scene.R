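# Shared small-scene fixtures, built once per test session.

.scene_cache <- new.env(parent = emptyenv())

scene_stack <- function(sc) {
  stack <- c(lapply(1:4, function(b) sc$image[, , b]), list(sc$dsm))
  names(stack) <- c("blue", "green", "red", "nir", "dsm")
  stack
}

# a segmented + featured small scene with belt assignment, memoized by key
small_scene_run <- function(key = "default", seed = 7L, rows = 192L,
                            cols = 96L, scale = 10, ...) {
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- synth_scene(rows = rows, cols = cols, seed = seed, ...)
  l2 <- segment(scene_stack(sc),
                segmentation_params(scale = scale,
                                    band_weights = c(1, 1, 1, 2, 0.05)))
  f2 <- compute_features(l2, sc$image, sc$dsm)
  slopes <- split_slopes(sc$dsm)
  belts <- build_constraint_raster(sc$dsm, slopes, sc$table)
  ba <- assign_objects(l2, belts)
  truth_class <- sc$legend$class[vegbelt:::majority_labels_(l2, sc$truth)]
  out <- list(scene = sc, objects = l2, features = f2, slopes = slopes,
              belts = belts, belt_assign = ba, truth_class = truth_class)
  .scene_cache[[key]] <- out
  out
}

# wrap a plain feature matrix + ids into a sample_set for purity helpers
make_sample_set <- function(formation, ids, brightness, stage = "initial",
                            slope = "north") {
  vegbelt:::new_sample_set_(formation, slope, ids, stage, brightness)
}
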