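#' Confusion matrix
#'
#' Counts with **rows = predicted** class and **columns = reference** class
#' (so the user-accuracy column of a printed matrix is row-wise); this
#' orientation matches the published worked examples and is fixed because
#' conventions vary.
#'
#' @param pred,ref equal-length label vectors.
#' @param classes ordered class names; defaults to the classes present (in
#'   order of first appearance in `ref` then `pred`).
#' @return a `confusion_matrix`: integer matrix with class dimnames.
#' @export
confusion <- function(pred, ref, classes = NULL) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(pred) == 0L) stop("empty input")
  pred <- as.character(pred)
  ref <- as.character(ref)
  if (is.null(classes)) classes <- unique(c(ref, pred))
  bad <- setdiff(unique(c(pred, ref)), classes)
  if (length(bad)) stop("labels outside the class list: ",
                        paste(bad, collapse = ", "))
  m <- table(factor(pred, levels = classes), factor(ref, levels = classes))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("predicted", "reference")
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Assemble a confusion matrix from pre-tabulated counts
#'
#' @param counts square integer matrix (rows = predicted).
#' @param classes class names (defaults to rownames).
#' @return a `confusion_matrix`.
#' @export
as_confusion <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = classes, reference = classes)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Read a confusion-matrix CSV (first column = predicted class names)
#' @param path CSV path.
#' @return a `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_confusion(as.matrix(d[, -1L]), classes = d[[1L]])
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (%d classes, N = %d): OA %.1f%%, kappa %.3f\n",
              nrow(x), sum(x), 100 * overall_accuracy(x), kappa(x)))
  print(unclass(x))
  invisible(x)
}

#' Accuracy statistics of a confusion matrix
#'
#' `overall_accuracy` = trace / N. `user_accuracy` = diagonal / row total
#' (commission side), `producer_accuracy` = diagonal / column total
#' (omission side); empty denominators give `NA` with a `"undefined"`
#' attribute rather than 0. `kappa` = (p_o - p_e)/(1 - p_e) with
#' `p_e = sum(row_c * col_c) / N^2`; the degenerate `p_e = 1` case is 1 when
#' `p_o = 1` and `NA` otherwise.
#'
#' @param m a `confusion_matrix`.
#' @param class class name for the per-class accuracies.
#' @return numeric scalar (or `NA` flagged as undefined).
#' @export
overall_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(m)) / n
}

#' @rdname overall_accuracy
#' @export
user_accuracy <- function(m, class) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!class %in% rownames(m)) stop("unknown class: ", class)
  tot <- sum(m[class, ])
  if (tot == 0) return(structure(NA_real_, undefined = TRUE))
  m[class, class] / tot
}

#' @rdname overall_accuracy
#' @export
producer_accuracy <- function(m, class) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!class %in% colnames(m)) stop("unknown class: ", class)
  tot <- sum(m[, class])
  if (tot == 0) return(structure(NA_real_, undefined = TRUE))
  m[class, class] / tot
}

#' @rdname overall_accuracy
#' @export
kappa <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) {
    return(if (po == 1) 1 else structure(NA_real_, undefined = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Sample accuracy of selected sample sets
#'
#' Fraction of sample objects whose majority ground-truth class equals the
#' intended formation. [sample_accuracy_report()] additionally reports means
#' by slope and by west/middle/east thirds (equal-width vertical thirds of
#' the raster), each weighted overall mean recombining to the global one.
#'
#' @param set a `sample_set`.
#' @param truth_class per-object majority truth class (character, aligned
#'   with `object_id`).
#' @param object_ids object ids aligned with `truth_class`.
#' @return fraction in `[0, 1]`.
#' @export
sample_accuracy <- function(set, truth_class, object_ids) {
  stopifnot(inherits(set, "sample_set"))
  if (length(set$ids) == 0L) stop("empty sample set")
  mean(truth_class[match(set$ids, object_ids)] == set$formation,
       na.rm = TRUE)
}

#' @rdname sample_accuracy
#' @param db a `sample_db`.
#' @param features feature table (for object ids).
#' @param objects the `object_map` (for object centroids / regional thirds).
#' @return data.frame per set with overall/regional accuracies, plus
#'   attribute `"summary"` with slope / region / overall means.
#' @export
sample_accuracy_report <- function(db, truth_class, features, objects) {
  stopifnot(inherits(db, "sample_db"))
  cc <- as.numeric(col(objects$labels))
  grp <- factor(as.numeric(objects$labels),
                levels = seq_len(objects$n_objects))
  obj_col <- as.numeric(tapply(cc, grp, mean))
  third <- cut(obj_col, breaks = 3L, labels = c("west", "middle", "east"))
  rows <- NULL
  for (nm in names(db$sets)) {
    s <- db$sets[[nm]]
    idx <- match(s$ids, features$object_id)
    ok <- truth_class[idx] == s$formation
    reg <- tapply(ok, third[idx], mean)
    rows <- rbind(rows, data.frame(
      set = nm, slope = s$slope, formation = s$formation,
      n = length(s$ids), accuracy = mean(ok, na.rm = TRUE),
      west = as.numeric(reg["west"]), middle = as.numeric(reg["middle"]),
      east = as.numeric(reg["east"]), stringsAsFactors = FALSE))
  }
  summary <- list(
    overall = sum(rows$accuracy * rows$n) / sum(rows$n),
    by_slope = tapply(rows$accuracy * rows$n, rows$slope, sum) /
      tapply(rows$n, rows$slope, sum))
  attr(rows, "summary") <- summary
  rows
}

#' Random validation points
#'
#' Draws `n` uniform random valid pixels (both rasters non-NA), builds the
#' confusion matrix of predicted vs reference labels at those points and
#' returns the mismatching points as coordinates.
#'
#' @param pred_raster,ref_raster co-registered label matrices (integer codes
#'   or characters).
#' @param n number of points (default 1000).
#' @param classes ordered class names for the confusion matrix.
#' @param seed integer seed.
#' @return list: `confusion`, `error_points` (data.frame `row`, `col`,
#'   `pred`, `ref`), `n`.
#' @export
validation_points <- function(pred_raster, ref_raster, n = 1000L,
                              classes = NULL, seed = 1L) {
  stopifnot(identical(dim(pred_raster), dim(ref_raster)), n >= 1L)
  valid <- which(!is.na(pred_raster) & !is.na(ref_raster))
  if (length(valid) < n) stop("fewer than n valid pixels")
  pts <- with_seed_(seed, sample(valid, n))
  pred <- as.character(pred_raster[pts])
  ref <- as.character(ref_raster[pts])
  cm <- confusion(pred, ref, classes)
  bad <- pred != ref
  err <- data.frame(row = ((pts - 1L) %% nrow(pred_raster)) + 1L,
                    col = ((pts - 1L) %/% nrow(pred_raster)) + 1L,
                    pred = pred, ref = ref)[bad, , drop = FALSE]
  rownames(err) <- NULL
  list(confusion = cm, error_points = err, n = n)
}
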