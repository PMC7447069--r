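#' Segmentation parameters
#'
#' Parameters of the multiresolution region-merging segmentation. The merge
#' cost blends colour heterogeneity (weighted per layer) with shape
#' heterogeneity; `shape_factor` is the weight of the shape term (colour
#' weight is `1 - shape_factor`) and `compactness` splits the shape term
#' between compactness and smoothness. Merging stops when the cheapest merge
#' cost reaches `scale^2`.
#'
#' Defaults mirror the two-layer protocol used for the real imagery: layer 1
#' (non-vegetation extraction) at scale 360 and layer 2 (vegetation) at scale
#' 140, both with shape factor 0.2 and compactness 0.6, and NIR weighted 2
#' against 1 for the other layers.
#'
#' @param scale non-negative scale parameter; 0 leaves every pixel its own
#'   object.
#' @param shape_factor shape weight in `[0, 1]`.
#' @param compactness compactness weight in `[0, 1]`.
#' @param band_weights non-negative per-layer weights, recycled or checked
#'   against the stack at segmentation time. `NULL` = NIR-weighted default
#'   (2 for a layer named "nir", 1 otherwise).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(scale = 140, shape_factor = 0.2,
                                compactness = 0.6, band_weights = NULL) {
  stopifnot(scale >= 0, shape_factor >= 0, shape_factor <= 1,
            compactness >= 0, compactness <= 1)
  if (!is.null(band_weights)) {
    stopifnot(all(band_weights >= 0), any(band_weights > 0))
  }
  structure(list(scale = scale, shape_factor = shape_factor,
                 compactness = compactness, band_weights = band_weights),
            class = "segmentation_params")
}

# normalize a stack argument (matrix, 3-d array or list of matrices) to a
# list of matrices, carrying layer names when present
as_stack_ <- function(stack) {
  if (is.matrix(stack)) stack <- list(layer1 = stack)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    nms <- dimnames(stack)[[3]]
    stack <- lapply(seq_len(dim(stack)[3]), function(l) stack[, , l])
    names(stack) <- if (is.null(nms)) paste0("layer", seq_along(stack)) else nms
  }
  stopifnot(is.list(stack), length(stack) >= 1L)
  d <- dim(stack[[1L]])
  if (is.null(d) || any(d < 1L)) stop("empty raster")
  for (m in stack) if (!identical(dim(m), d)) stop("layers not co-registered")
  stack
}

stack_weights_ <- function(stack, params) {
  w <- params$band_weights
  if (is.null(w)) {
    w <- rep(1, length(stack))
    nms <- names(stack)
    if (!is.null(nms)) w[tolower(nms) == "nir"] <- 2
  }
  if (length(w) != length(stack)) {
    stop("band_weights length ", length(w), " != number of layers ",
         length(stack))
  }
  w
}

#' Multiresolution region-merging segmentation
#'
#' Bottom-up pairwise merging starting from single-pixel objects: at every
#' step the globally cheapest adjacent pair (which is always a mutual best
#' fit) is merged, until the cheapest merge cost reaches `scale^2`. The cost
#' is the increase in weighted colour heterogeneity (`n * sd` per layer)
#' blended with compactness/smoothness shape heterogeneity. Deterministic:
#' ties break on (cost, lower object id).
#'
#' @param stack a matrix, `rows x cols x L` array, or list of co-registered
#'   matrices (layer names are used for default band weighting).
#' @param params a [segmentation_params] object.
#' @return An `object_map`: list with `labels` (integer matrix, ids `1..n`
#'   in raster-scan order of first occurrence), `n_objects`, `params`.
#' @export
segment <- function(stack, params = segmentation_params()) {
  stack <- as_stack_(stack)
  w <- stack_weights_(stack, params)
  d <- dim(stack[[1L]])
  if (anyNA(stack[[1L]])) stop("NA pixels are not supported in segmentation")
  flat <- unlist(lapply(stack, as.numeric), use.names = FALSE)
  labels <- cpp_segment(flat, d[1L], d[2L], length(stack), w,
                        params$shape_factor, params$compactness,
                        params$scale)
  structure(list(labels = labels, n_objects = max(labels), params = params),
            class = "object_map")
}

#' @export
print.object_map <- function(x, ...) {
  cat("object map:", x$n_objects, "objects on a", nrow(x$labels), "x",
      ncol(x$labels), "raster (scale", x$params$scale, ")\n")
  invisible(x)
}

#' Mean-variance curve over candidate segmentation scales
#'
#' For each scale, segments the stack and computes the area-weighted
#' between-object variance of object mean brightness (brightness = mean of
#' the first four spectral layers). Purer objects contrast more with their
#' neighbours, raising the between-object variance, so the curve peaks near
#' a good scale.
#'
#' @inheritParams segment
#' @param scales ascending positive scales (the broken-line graph in the
#'   source protocol scanned 100 to 500).
#' @param spectral_layers indices of the spectral layers used for brightness
#'   (default 1:4).
#' @return data.frame with columns `scale`, `mean_variance`, `n_objects`.
#' @export
mean_variance_curve <- function(stack, params = segmentation_params(),
                                scales, spectral_layers = NULL) {
  stack <- as_stack_(stack)
  stopifnot(length(scales) >= 1L, all(scales > 0),
            !is.unsorted(scales, strictly = FALSE))
  if (is.null(spectral_layers)) {
    spectral_layers <- seq_len(min(4L, length(stack)))
  }
  bright <- Reduce(`+`, stack[spectral_layers]) / length(spectral_layers)
  out <- lapply(scales, function(s) {
    p <- params
    p$scale <- s
    om <- segment(stack, p)
    mu <- as.numeric(tapply(as.numeric(bright), as.numeric(om$labels), mean))
    n <- as.numeric(table(om$labels))
    grand <- sum(n * mu) / sum(n)
    data.frame(scale = s,
               mean_variance = sum(n * (mu - grand)^2) / sum(n),
               n_objects = om$n_objects)
  })
  do.call(rbind, out)
}

#' Select a segmentation scale from a mean-variance curve
#'
#' Returns the scale at the curve maximum; ties break toward the smaller
#' scale. A maximum at either endpoint triggers a warning (the scanned range
#' probably does not bracket the peak).
#'
#' @param curve data.frame with columns `scale` and a value column (second
#'   column, e.g. `mean_variance`).
#' @return the selected scale (numeric scalar).
#' @export
select_scale <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) stop("empty mean-variance curve")
  v <- curve[[2L]]
  i <- which(v == max(v))[1L]
  if (i == 1L || i == nrow(curve)) {
    warning("mean-variance maximum at the boundary of the scanned scales")
  }
  curve$scale[i]
}

#' Per-object feature table
#'
#' One row per object: per-band means, brightness (mean of the four band
#' means), NDVI/DVI/RVI from the object's NIR and Red means, Max.Diff
#' (largest absolute pairwise band-mean difference over brightness), GLCM
#' contrast and entropy (8 grey levels on the NIR band, distance 1,
#' symmetric, averaged over 4 directions, natural-log entropy), area in
#' pixels, length/width (major/minor axis ratio of the second-moment
#' ellipse) and mean DSM elevation.
#'
#' Objects whose Red mean is 0 get `rvi = NA` and `rvi_defined = FALSE`
#' rather than being dropped.
#'
#' @param objects an `object_map` from [segment()].
#' @param image `rows x cols x 4` band array (blue, green, red, nir).
#' @param dsm elevation matrix.
#' @return data.frame keyed by `object_id`.
#' @export
compute_features <- function(objects, image, dsm) {
  stopifnot(inherits(objects, "object_map"))
  labels <- objects$labels
  stopifnot(identical(dim(labels), dim(image)[1:2]),
            identical(dim(labels), dim(dsm)))
  n <- objects$n_objects
  idx <- as.numeric(labels)
  grp <- factor(idx, levels = seq_len(n))
  mean_by <- function(v) as.numeric(tapply(v, grp, mean))
  bm <- matrix(vapply(1:4, function(b) mean_by(as.numeric(image[, , b])),
                      numeric(n)), nrow = n,
               dimnames = list(NULL, c("mean_blue", "mean_green",
                                       "mean_red", "mean_nir")))
  brightness <- rowMeans(bm)
  ndvi <- (bm[, "mean_nir"] - bm[, "mean_red"]) /
    (bm[, "mean_nir"] + bm[, "mean_red"])
  dvi <- bm[, "mean_nir"] - bm[, "mean_red"]
  rvi_defined <- bm[, "mean_red"] > 0
  rvi <- ifelse(rvi_defined, bm[, "mean_nir"] / bm[, "mean_red"], NA_real_)
  max_diff <- apply(bm, 1, function(v) max(abs(outer(v, v, "-")))) /
    ifelse(brightness > 0, brightness, NA_real_)

  area <- as.numeric(table(grp))
  rr <- as.numeric(row(labels))
  cc <- as.numeric(col(labels))
  mr <- mean_by(rr); mc <- mean_by(cc)
  vrr <- mean_by(rr^2) - mr^2
  vcc <- mean_by(cc^2) - mc^2
  vrc <- mean_by(rr * cc) - mr * mc
  # + 1/12: second moment of the unit pixel, keeps single pixels well-defined
  vrr <- vrr + 1 / 12
  vcc <- vcc + 1 / 12
  tr <- vrr + vcc
  det <- vrr * vcc - vrc^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 1e-12)
  length_width <- sqrt(l1 / l2)

  nir <- image[, , "nir"]
  rng <- range(nir, na.rm = TRUE)
  qv <- if (diff(rng) > 0) {
    pmin(pmax(1, ceiling((as.numeric(nir) - rng[1]) / diff(rng) * 8)), 8)
  } else {
    rep(1, length(nir))
  }
  q <- matrix(as.integer(qv), nrow(nir), ncol(nir))
  glcm <- cpp_glcm(labels, q, n, 8L)

  data.frame(object_id = seq_len(n), bm, brightness = brightness,
             ndvi = ndvi, dvi = dvi, rvi = rvi, rvi_defined = rvi_defined,
             max_diff = max_diff, glcm_contrast = glcm[, 1],
             glcm_entropy = glcm[, 2], area = area,
             length_width = length_width, dsm_mean = mean_by(as.numeric(dsm)))
}

#' Clustering feature columns
#'
#' The features the sample selector clusters on: per-band means, brightness,
#' NDVI, DVI, RVI and Max.Diff.
#' @return character vector of column names.
#' @export
clustering_features <- function() {
  c("mean_blue", "mean_green", "mean_red", "mean_nir", "brightness",
    "ndvi", "dvi", "rvi", "max_diff")
}
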