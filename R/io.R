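#' Plain-text raster I/O (ESRI ASCII grid)
#'
#' Single-band rasters travel as ESRI ASCII grids (`.asc`): a 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of numbers, top row first. Multiband images are written as one file
#' per band. This is the package's interchange format for elevation, object
#' id, belt and label rasters.
#'
#' @param m numeric/integer matrix.
#' @param path output path.
#' @param cellsize pixel size in metres (default 10).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata value written for `NA` (default -9999).
#' @export
write_ascii_grid <- function(m, path, cellsize = 10, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", xll), paste("yllcorner", yll),
               paste("cellsize", cellsize), paste("NODATA_value", nodata)),
             con)
  mm <- m
  mm[is.na(mm)] <- nodata
  utils::write.table(mm, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid`: the matrix, with header fields as attributes.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2L])
  names(vals) <- tolower(kv[, 1L])
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  attr(m, "xllcorner") <- vals[["xllcorner"]]
  attr(m, "yllcorner") <- vals[["yllcorner"]]
  m
}

#' Write point features as GeoJSON
#'
#' Used for sample-object centroids and validation error points; attributes
#' are carried per feature. Coordinates are pixel-centre x/y in raster
#' units.
#'
#' @param df data.frame with `x`, `y` columns plus attribute columns.
#' @param path output path.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
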