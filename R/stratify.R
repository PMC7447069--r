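#' Split a scene into north and south slopes along the main ridgeline
#'
#' The ridgeline is taken as the per-column row of maximum elevation (ties to
#' the smaller row index), median-smoothed over an 11-column window. Pixels
#' at or above the ridgeline row (smaller row index) are "north", pixels
#' below are "south"; ridge pixels themselves count as north. Works for
#' scenes with a single dominant east-west ridge; watershed-divide analysis
#' would be needed for general terrain.
#'
#' @param dsm elevation matrix.
#' @param window odd median-smoothing window in columns (default 11).
#' @return A `slope_mask`: list with `mask` (integer matrix, 1 = north,
#'   2 = south) and `ridge` (per-column ridge row).
#' @export
split_slopes <- function(dsm, window = 11L) {
  stopifnot(is.matrix(dsm))
  if (max(dsm) - min(dsm) <= 0) {
    stop("flat DSM: no unique ridgeline")
  }
  ridge <- apply(dsm, 2, which.max)
  if (ncol(dsm) >= 3L) {
    k <- min(window, ncol(dsm))
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) ridge <- as.integer(stats::runmed(ridge, k))
  }
  mask <- matrix(2L, nrow(dsm), ncol(dsm))
  for (j in seq_len(ncol(dsm))) mask[seq_len(ridge[j]), j] <- 1L
  structure(list(mask = mask, ridge = ridge,
                 levels = c("north", "south")), class = "slope_mask")
}

#' Rasterize the MAB belts over a DSM (terrain constraint factor)
#'
#' Every pixel gets the `belt_id` of the belt containing its elevation on
#' its slope side; pixels above the table summit are `NA` (no-data).
#' Deterministic in (dsm, mask, table).
#'
#' @param dsm elevation matrix.
#' @param mask a `slope_mask` from [split_slopes()].
#' @param table a [mab_table].
#' @return A `belt_raster`: list with `belt_ids` (integer matrix of
#'   `table$belt_id` codes) and `legend` (the belt table).
#' @export
build_constraint_raster <- function(dsm, mask, table = load_mab_table()) {
  stopifnot(inherits(mask, "slope_mask"), identical(dim(dsm), dim(mask$mask)))
  belt <- matrix(NA_integer_, nrow(dsm), ncol(dsm))
  north <- mask$mask == 1L
  belt[north] <- belt_at_vec_(table, "north", dsm[north])
  belt[!north] <- belt_at_vec_(table, "south", dsm[!north])
  structure(list(belt_ids = belt, legend = as.data.frame(table)),
            class = "belt_raster")
}

#' Assign segmentation objects to belts
#'
#' Each object takes the belt covering the majority of its pixels; ties
#' break toward the lower-altitude belt, and objects whose majority cover is
#' no-data stay unassigned (`NA`).
#'
#' @param objects an `object_map`.
#' @param belts a `belt_raster`.
#' @return integer vector of `belt_id` per object (length `n_objects`).
#' @export
assign_objects <- function(objects, belts) {
  stopifnot(inherits(objects, "object_map"), inherits(belts, "belt_raster"),
            identical(dim(objects$labels), dim(belts$belt_ids)))
  n <- objects$n_objects
  lab <- as.numeric(objects$labels)
  b <- as.numeric(belts$belt_ids)
  b[is.na(b)] <- 0 # code no-data as belt 0 so it competes in the majority
  counts <- table(factor(lab, levels = seq_len(n)), b)
  bvals <- as.numeric(colnames(counts))
  # order candidate belts by (count desc, alt_lo asc); belt 0 = no-data
  alt_lo <- rep(Inf, length(bvals))
  hit <- match(bvals, belts$legend$belt_id)
  alt_lo[!is.na(hit)] <- belts$legend$alt_lo[hit[!is.na(hit)]]
  out <- integer(n)
  for (i in seq_len(n)) {
    cnt <- as.numeric(counts[i, ])
    best <- order(-cnt, alt_lo)[1L]
    out[i] <- if (bvals[best] == 0) NA_integer_ else as.integer(bvals[best])
  }
  out
}

# majority label of a label raster per object (NA labels lose ties)
majority_labels_ <- function(objects, labels) {
  n <- objects$n_objects
  lab <- as.numeric(objects$labels)
  v <- as.numeric(labels)
  v[is.na(v)] <- -1
  counts <- unclass(table(factor(lab, levels = seq_len(n)), v)) * 1.0
  vals <- as.numeric(colnames(counts))
  counts[, vals == -1] <- counts[, vals == -1] - 0.5 # NA loses ties
  out <- vals[apply(counts, 1, which.max)]
  out[out == -1] <- NA_real_
  out
}
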