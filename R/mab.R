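#' Mountain altitudinal belt (MAB) tables
#'
#' A MAB table lists, for each slope of a mountain (north / south), the
#' vegetation formations in order of altitude together with the altitude
#' interval each formation occupies. It is the prior knowledge that drives
#' belt stratification, automatic sample selection and cluster-count choice.
#'
#' Altitude intervals are half-open `[alt_lo, alt_hi)` so that a boundary
#' altitude shared by two adjacent belts belongs to exactly one of them; the
#' topmost belt of each slope is additionally closed at the top so the summit
#' pixel is classified.
#'
#' @param belts data.frame with columns `slope` ("north"/"south"),
#'   `formation` (non-empty character), `alt_lo`, `alt_hi` (metres).
#' @return A validated `mab_table` (a data.frame ordered by slope then
#'   `alt_lo`).
#' @examples
#' tab <- load_mab_table()             # packaged Taibai Mountain table
#' belt_at(tab, "north", 2100)$formation
#' @export
mab_table <- function(belts) {
  stopifnot(is.data.frame(belts))
  need <- c("slope", "formation", "alt_lo", "alt_hi")
  if (!all(need %in% names(belts))) {
    stop("belt table needs columns: ", paste(need, collapse = ", "))
  }
  belts$slope <- as.character(belts$slope)
  belts$formation <- as.character(belts$formation)
  belts$alt_lo <- as.numeric(belts$alt_lo)
  belts$alt_hi <- as.numeric(belts$alt_hi)
  if (any(!belts$slope %in% c("north", "south"))) {
    stop("slope must be 'north' or 'south'")
  }
  if (any(is.na(belts$alt_lo)) || any(is.na(belts$alt_hi))) {
    stop("altitude ranges must be numeric")
  }
  if (any(!nzchar(belts$formation))) stop("formation names must be non-empty")
  if (any(belts$alt_lo < 0)) stop("alt_lo must be >= 0")
  if (any(belts$alt_lo >= belts$alt_hi)) stop("alt_lo must be < alt_hi")
  out <- NULL
  for (sl in c("north", "south")) {
    b <- belts[belts$slope == sl, , drop = FALSE]
    if (nrow(b) == 0L) next
    b <- b[order(b$alt_lo), , drop = FALSE]
    if (nrow(b) > 1L) {
      lo <- b$alt_lo[-1L]
      hi <- b$alt_hi[-nrow(b)]
      bad <- which(lo != hi)
      if (length(bad)) {
        i <- bad[1L]
        kind <- if (lo[i] < hi[i]) "overlapping" else "gapped"
        stop(sprintf(
          "%s belts on %s slope: '%s' [%g, %g) vs '%s' [%g, %g)",
          kind, sl, b$formation[i], b$alt_lo[i], b$alt_hi[i],
          b$formation[i + 1L], b$alt_lo[i + 1L], b$alt_hi[i + 1L]))
      }
    }
    out <- rbind(out, b)
  }
  if (is.null(out)) stop("belt table is empty")
  rownames(out) <- NULL
  out$belt_id <- seq_len(nrow(out))
  class(out) <- c("mab_table", "data.frame")
  out
}

#' Load a MAB table from a plain-text config file
#'
#' The file is tab-separated with a header line
#' `slope formation alt_lo alt_hi`; lines starting with `#` are comments.
#' With `path = NULL` the packaged default for Taibai Mountain (Qinling
#' Mountains, summit 3771.2 m) is loaded: 9 belts on the north slope and 8 on
#' the south slope (the *Quercus liaotungensis* forest occurs only on the
#' north slope).
#'
#' @param path config-file path, or `NULL` for the packaged Taibai table.
#' @return A validated [mab_table].
#' @export
load_mab_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taibai_mab.tsv", package = "vegbelt")
  }
  if (!file.exists(path)) stop("MAB table file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  mab_table(raw)
}

#' @export
print.mab_table <- function(x, ...) {
  cat("MAB table:", nrow(x), "belts",
      sprintf("(north %d, south %d)\n",
              sum(x$slope == "north"), sum(x$slope == "south")))
  print.data.frame(x, ...)
  invisible(x)
}

check_slope_ <- function(slope) {
  if (length(slope) != 1L || !slope %in% c("north", "south")) {
    stop("slope must be 'north' or 'south'")
  }
  slope
}

#' Belt containing a given altitude
#'
#' Intervals are half-open `[alt_lo, alt_hi)`; the topmost belt of the slope
#' is closed at the top. Altitudes below the lowest belt or above the summit
#' return `NULL`.
#'
#' @param table a [mab_table].
#' @param slope "north" or "south".
#' @param altitude metres.
#' @return A one-row data.frame (the belt) or `NULL`.
#' @export
belt_at <- function(table, slope, altitude) {
  stopifnot(inherits(table, "mab_table"), is.numeric(altitude),
            length(altitude) == 1L)
  check_slope_(slope)
  b <- table[table$slope == slope, , drop = FALSE]
  if (nrow(b) == 0L) stop("no belts for slope ", slope)
  top <- max(b$alt_hi)
  hit <- which(altitude >= b$alt_lo &
                 (altitude < b$alt_hi | (altitude == top & b$alt_hi == top)))
  if (length(hit) == 0L) return(NULL)
  b[hit[1L], , drop = FALSE]
}

#' Vectorised belt lookup (internal work-horse for rasterization)
#'
#' @return integer vector of `belt_id` values (NA outside the table).
#' @keywords internal
belt_at_vec_ <- function(table, slope, altitude) {
  b <- table[table$slope == slope, , drop = FALSE]
  top <- max(b$alt_hi)
  # findInterval over the contiguous breaks [lo_1, hi_1=lo_2, ..., hi_k]
  breaks <- c(b$alt_lo, top)
  idx <- findInterval(altitude, breaks, rightmost.closed = TRUE)
  out <- rep(NA_integer_, length(altitude))
  ok <- idx >= 1L & idx <= nrow(b) & !is.na(altitude)
  out[ok] <- b$belt_id[idx[ok]]
  out
}

#' Formations whose belt lies near an altitude range
#'
#' Returns every formation on the given slope whose belt interval intersects
#' the widened window `[alt_lo - near_delta, alt_hi + near_delta)`; the Basal
#' zone is excluded (it holds cultivated land and settlements, not a
#' vegetation formation). Intersection uses the half-open convention, so with
#' `near_delta = 0` an exactly adjacent belt is not included.
#'
#' @inheritParams belt_at
#' @param alt_lo,alt_hi altitude range of the belt of interest (metres).
#' @param near_delta window widening (metres); default 200, roughly one
#'   sub-belt width.
#' @return Character vector of formation names (in altitude order).
#' @export
formations_near <- function(table, slope, alt_lo, alt_hi, near_delta = 200) {
  stopifnot(inherits(table, "mab_table"), alt_lo < alt_hi, near_delta >= 0)
  check_slope_(slope)
  b <- table[table$slope == slope, , drop = FALSE]
  lo <- alt_lo - near_delta
  hi <- alt_hi + near_delta
  keep <- b$alt_lo < hi & b$alt_hi > lo
  keep <- keep & !is_basal_(b$formation)
  res <- b$formation[keep]
  if (length(res) == 0L) {
    stop("no formations near [", alt_lo, ", ", alt_hi, ") on ", slope,
         " slope: range outside the belt table")
  }
  res
}

is_basal_ <- function(formation) {
  grepl("^basal", tolower(formation))
}

#' Sampling parameters
#'
#' @param k_multiplier clusters per nearby formation (default 3: the cluster
#'   count is three times the number of possible formations near the belt).
#' @param near_delta metres; window for "nearby" formations (default 200).
#' @param target_n target corrected-sample count per formation (default 120).
#' @param top_m how many of the largest clusters are compared against the
#'   formation prototype (default 5; must lie in 3..5).
#' @param balance_tol standardized inter-centroid distance below which the two
#'   correction clusters are considered "roughly the same" (default 1.0).
#' @param max_iter maximum correction iterations (default 10).
#' @param min_keep minimum surviving samples before sampling for a formation
#'   is declared failed (default 10).
#' @return A `sampling_params` list.
#' @export
sampling_params <- function(k_multiplier = 3L, near_delta = 200,
                            target_n = 120L, top_m = 5L, balance_tol = 1.0,
                            max_iter = 10L, min_keep = 10L) {
  stopifnot(k_multiplier >= 1L, target_n >= 1L, top_m >= 3L, top_m <= 5L,
            near_delta >= 0, balance_tol >= 0, max_iter >= 1L, min_keep >= 1L)
  structure(list(k_multiplier = as.integer(k_multiplier),
                 near_delta = near_delta, target_n = as.integer(target_n),
                 top_m = as.integer(top_m), balance_tol = balance_tol,
                 max_iter = as.integer(max_iter),
                 min_keep = as.integer(min_keep)),
            class = "sampling_params")
}

#' Number of clusters for a belt
#'
#' Three times (by default) the number of possible vegetation formations near
#' the altitude of the belt.
#'
#' @param n_formations number of nearby formations (>= 1).
#' @param params a [sampling_params] object.
#' @return integer cluster count.
#' @export
cluster_count <- function(n_formations, params = sampling_params()) {
  stopifnot(is.numeric(n_formations), length(n_formations) == 1L)
  if (n_formations < 1) stop("n_formations must be >= 1")
  as.integer(params$k_multiplier * n_formations)
}
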