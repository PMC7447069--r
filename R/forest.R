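#' Random forest classifier
#'
#' Bagged CART trees (gini impurity) with per-split random feature
#' subsampling, grown by the package's compiled tree core. Parameter names
#' follow the common ML convention: `n_estimators` trees, `max_depth`,
#' `max_features` candidate features per split, `min_samples_leaf` minimum
#' leaf size. Deterministic under a fixed seed; prediction ties break toward
#' the lowest class index.
#'
#' @param x numeric matrix/data.frame of features.
#' @param y factor (or coercible) class labels.
#' @param n_estimators number of trees (default 20).
#' @param max_depth maximum tree depth (default 19).
#' @param max_features candidate features per split; default
#'   `min(8, ncol(x))`.
#' @param min_samples_leaf minimum samples per leaf (default 2).
#' @param seed integer seed.
#' @return an `rf_model`.
#' @export
rf_fit <- function(x, y, n_estimators = 20L, max_depth = 19L,
                   max_features = NULL, min_samples_leaf = 2L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor_c_(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (is.null(max_features)) max_features <- min(8L, ncol(x))
  max_features <- min(max_features, ncol(x))
  n <- nrow(x)
  with_seed_(seed, {
    trees <- vector("list", n_estimators)
    imp <- numeric(ncol(x))
    for (t in seq_len(n_estimators)) {
      boot <- sample.int(n, n, replace = TRUE)
      trees[[t]] <- cpp_cart_grow(x, as.integer(y), nlevels(y), boot,
                                  as.integer(max_features),
                                  as.integer(max_depth),
                                  as.integer(min_samples_leaf))
      imp <- imp + trees[[t]]$importance
    }
    imp <- if (sum(imp) > 0) imp / sum(imp) else imp
    names(imp) <- colnames(x)
    structure(list(trees = trees, levels = levels(y), importance = imp,
                   features = colnames(x),
                   params = list(n_estimators = n_estimators,
                                 max_depth = max_depth,
                                 max_features = max_features,
                                 min_samples_leaf = min_samples_leaf,
                                 seed = seed)),
              class = "rf_model")
  })
}

#' @rdname rf_fit
#' @param model an `rf_model`.
#' @param newdata feature matrix to predict.
#' @return factor of predicted classes.
#' @export
rf_predict <- function(model, newdata) {
  x <- as.matrix(newdata)
  if (!is.null(model$features)) x <- x[, model$features, drop = FALSE]
  storage.mode(x) <- "double"
  k <- length(model$levels)
  votes <- matrix(0L, nrow(x), k)
  for (tr in model$trees) {
    p <- cpp_cart_predict(tr, x)
    votes[cbind(seq_len(nrow(x)), p)] <- votes[cbind(seq_len(nrow(x)), p)] + 1L
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

#' k-nearest-neighbour classifier
#'
#' Euclidean KNN with uniform weights. Vote ties break toward the tied class
#' with the nearest single neighbour (deterministic).
#'
#' @param train,test numeric feature matrices.
#' @param cl training class labels.
#' @param k neighbours (default 9).
#' @return factor of predicted classes for `test`.
#' @export
knn_predict <- function(train, test, cl, k = 9L) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  cl <- factor_c_(cl)
  k <- min(k, nrow(train))
  # squared distances via the expansion ||a-b||^2 = a^2 + b^2 - 2ab
  d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
    2 * test %*% t(train)
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    ord <- order(d2[i, ])[seq_len(k)]
    tab <- table(cl[ord])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      first <- ord[match(TRUE, as.character(cl[ord]) %in% top)]
      out[i] <- as.character(cl[first])
    } else out[i] <- top
  }
  factor(out, levels = levels(cl))
}
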