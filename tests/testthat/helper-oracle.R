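# Brute-force greedy region-merging oracle, independent of the compiled
# implementation: every step recomputes ALL adjacent pair costs from scratch
# off the current label matrix (no incremental state), picks the cheapest
# pair (ties: lower min-id, then lower max-id; region id = smallest original
# pixel id, row-major 0-based) and merges it while the cost stays below
# scale^2. Arithmetic mirrors the documented cost definition exactly so
# integer-valued test images give bit-identical costs.

oracle_region_stats <- function(lab, id, layers) {
  pix <- which(lab == id)
  n <- length(pix)
  sums <- vapply(layers, function(m) sum(m[pix]), numeric(1))
  ssqs <- vapply(layers, function(m) sum(m[pix]^2), numeric(1))
  rr <- ((pix - 1) %% nrow(lab)) + 1
  cc <- ((pix - 1) %/% nrow(lab)) + 1
  # perimeter = exposed pixel edges
  per <- 0
  for (p in seq_len(n)) {
    r <- rr[p]; c <- cc[p]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nrow(lab) || c2 < 1 || c2 > ncol(lab) ||
          lab[r2, c2] != id) per <- per + 1
    }
  }
  list(n = n, sum = sums, ssq = ssqs, perim = per,
       rmin = min(rr), rmax = max(rr), cmin = min(cc), cmax = max(cc))
}

oracle_color_h <- function(st, w) {
  h <- 0
  for (l in seq_along(w)) {
    mean <- st$sum[l] / st$n
    v <- st$ssq[l] / st$n - mean * mean
    if (v < 0) v <- 0
    h <- h + w[l] * st$n * sqrt(v)
  }
  h
}

oracle_bboxp <- function(rmin, rmax, cmin, cmax) {
  2 * ((rmax - rmin + 1) + (cmax - cmin + 1))
}

oracle_merge_cost <- function(a, b, shared, w, shape_factor, cmpct) {
  w_color <- 1 - shape_factor
  n_m <- a$n + b$n
  dcol <- 0
  for (l in seq_along(w)) {
    s <- a$sum[l] + b$sum[l]
    q <- a$ssq[l] + b$ssq[l]
    mean <- s / n_m
    v <- q / n_m - mean * mean
    if (v < 0) v <- 0
    dcol <- dcol + w[l] * n_m * sqrt(v)
  }
  dcol <- dcol - oracle_color_h(a, w) - oracle_color_h(b, w)
  if (dcol < 0) dcol <- 0
  dshape <- 0
  if (w_color < 1) {
    perim_m <- a$perim + b$perim - 2 * shared
    rmin <- min(a$rmin, b$rmin); rmax <- max(a$rmax, b$rmax)
    cmin <- min(a$cmin, b$cmin); cmax <- max(a$cmax, b$cmax)
    hc <- sqrt(n_m) * perim_m -
      (sqrt(a$n) * a$perim + sqrt(b$n) * b$perim)
    hs <- n_m * perim_m / oracle_bboxp(rmin, rmax, cmin, cmax) -
      (a$n * a$perim / oracle_bboxp(a$rmin, a$rmax, a$cmin, a$cmax) +
       b$n * b$perim / oracle_bboxp(b$rmin, b$rmax, b$cmin, b$cmax))
    dshape <- cmpct * hc + (1 - cmpct) * hs
  }
  w_color * dcol + (1 - w_color) * dshape
}

# shared boundary length between two regions of a label matrix
oracle_shared <- function(lab, a, b) {
  s <- 0
  nr <- nrow(lab); nc <- ncol(lab)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] != a) next
    if (r < nr && lab[r + 1, c] == b) s <- s + 1
    if (r > 1 && lab[r - 1, c] == b) s <- s + 1
    if (c < nc && lab[r, c + 1] == b) s <- s + 1
    if (c > 1 && lab[r, c - 1] == b) s <- s + 1
  }
  s
}

brute_segment <- function(img, scale, shape_factor = 0, compactness = 0.6,
                          weights = NULL) {
  layers <- if (is.list(img)) img else list(img)
  if (is.null(weights)) weights <- rep(1, length(layers))
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  # region id = smallest original 0-based row-major pixel id in the region
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    lab[r, c] <- (r - 1) * nc + (c - 1)
  }
  thresh <- scale^2
  repeat {
    ids <- sort(unique(as.integer(lab)))
    if (length(ids) <= 1 || thresh <= 0) break
    stats <- lapply(ids, function(id) oracle_region_stats(lab, id, layers))
    names(stats) <- as.character(ids)
    best <- NULL
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      sh <- oracle_shared(lab, ids[i], ids[j])
      if (sh == 0) next
      cost <- oracle_merge_cost(stats[[i]], stats[[j]], sh, weights,
                                shape_factor, compactness)
      key <- c(cost, ids[i], ids[j])
      if (is.null(best) || cost < best[1] ||
          (cost == best[1] && (ids[i] < best[2] ||
                               (ids[i] == best[2] && ids[j] < best[3])))) {
        best <- key
      }
    }
    if (is.null(best) || best[1] >= thresh) break
    lab[lab == best[3]] <- best[2]
  }
  # canonical 1..n renumbering in raster-scan (row-major) first occurrence,
  # matching the implementation's output convention
  canon <- matrix(0L, nr, nc)
  nxt <- 0L
  seen <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    key <- as.character(lab[r, c])
    if (is.null(seen[[key]])) {
      nxt <- nxt + 1L
      seen[[key]] <- nxt
    }
    canon[r, c] <- seen[[key]]
  }
  canon
}

# canonicalize any label matrix the same way (for partition comparison)
canon_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  canon <- matrix(0L, nr, nc)
  nxt <- 0L
  seen <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    key <- as.character(lab[r, c])
    if (is.null(seen[[key]])) {
      nxt <- nxt + 1L
      seen[[key]] <- nxt
    }
    canon[r, c] <- seen[[key]]
  }
  canon
}
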