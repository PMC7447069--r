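# Clustering algorithm implementations used by cluster_candidates().
# All operate on an already z-scored numeric matrix and return integer
# labels (0 = noise, DBSCAN only). Only kmeans/hclust come from stats; the
# rest (GMM-EM, spectral, DBSCAN, mean shift) are authored here because the
# environment ships no clustering packages beyond base R.

kmeans_ <- function(x, k, seed) {
  with_seed_(seed, stats::kmeans(x, centers = k, nstart = 10L,
                                 iter.max = 100L))$cluster
}

agglomerative_ <- function(x, k) {
  stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = k)
}

gaussian_mixture_ <- function(x, k, seed, max_iter = 100L, tol = 1e-6) {
  n <- nrow(x); p <- ncol(x)
  km <- with_seed_(seed, stats::kmeans(x, centers = k, nstart = 5L,
                                       iter.max = 50L))
  mu <- km$centers
  sig <- matrix(1, k, p)
  pi_k <- as.numeric(table(factor(km$cluster, levels = 1:k))) / n
  pi_k <- pmax(pi_k, 1e-8)
  loglik <- -Inf
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in 1:k) {
      lg <- -0.5 * rowSums(sweep(sweep(x, 2, mu[j, ])^2, 2, sig[j, ], "/")) -
        0.5 * sum(log(2 * pi * sig[j, ]))
      resp[, j] <- log(pi_k[j]) + lg
    }
    m <- apply(resp, 1, max)
    resp <- exp(resp - m)
    rs <- rowSums(resp)
    ll <- sum(log(rs) + m)
    resp <- resp / rs
    nk <- pmax(colSums(resp), 1e-8)
    pi_k <- nk / n
    for (j in 1:k) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      sig[j, ] <- pmax(colSums(resp[, j] * sweep(x, 2, mu[j, ])^2) / nk[j],
                       1e-6)
    }
    if (is.finite(loglik) && abs(ll - loglik) < tol * abs(ll)) break
    loglik <- ll
  }
  max.col(resp, ties.method = "first")
}

spectral_ <- function(x, k, seed) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  sigma <- stats::median(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  a <- exp(-d^2 / (2 * sigma^2))
  diag(a) <- 0
  deg <- pmax(rowSums(a), 1e-12)
  l <- a / sqrt(deg) / rep(sqrt(deg), each = n) # D^-1/2 A D^-1/2
  ev <- eigen(l, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(u^2))
  u <- u / ifelse(nrm > 0, nrm, 1)
  with_seed_(seed, stats::kmeans(u, centers = k, nstart = 10L,
                                 iter.max = 100L))$cluster
}

# eps: knee (max second difference) of the sorted 4-NN distance curve,
# falling back to its 0.9 quantile when the knee is degenerate
dbscan_ <- function(x, min_pts = 5L) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  kdist <- apply(d, 1, function(v) sort(v)[min(min_pts, n)])
  s <- sort(kdist)
  eps <- if (n >= 5L) {
    d2 <- diff(diff(s))
    i <- which.max(d2) + 1L
    if (length(i) && is.finite(s[i]) && s[i] > 0) s[i] else
      stats::quantile(s, 0.9)
  } else stats::quantile(s, 0.9)
  if (!is.finite(eps) || eps <= 0) eps <- max(s) + 1e-9
  labels <- integer(n) # 0 = unvisited/noise
  cl <- 0L
  visited <- logical(n)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(d[i, ] <= eps)
    if (length(nb) < min_pts) next # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- which(d[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, setdiff(nb2, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

meanshift_ <- function(x, max_iter = 100L, tol = 1e-4) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  # local bandwidth: median 5-NN distance (a global median pairwise
  # distance spans cluster gaps and collapses well-separated groups)
  kk <- min(6L, n)
  h <- stats::median(apply(d, 1, function(v) sort(v)[kk]))
  if (!is.finite(h) || h <= 0) h <- 1
  modes <- x
  for (iter in seq_len(max_iter)) {
    shifted <- modes
    for (i in seq_len(n)) {
      w <- exp(-rowSums(sweep(x, 2, modes[i, ])^2) / (2 * h^2))
      shifted[i, ] <- colSums(w * x) / sum(w)
    }
    delta <- max(abs(shifted - modes))
    modes <- shifted
    if (delta < tol * h) break
  }
  # group modes closer than h/4
  labels <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (!is.null(centers)) {
      dd <- sqrt(colSums((t(centers) - modes[i, ])^2))
      j <- which(dd < h / 4)
      if (length(j)) {
        labels[i] <- j[1L]
        next
      }
    }
    centers <- rbind(centers, modes[i, ])
    labels[i] <- nrow(centers)
  }
  labels
}
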