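#' Default spectral signatures for the synthetic mountain scene
#'
#' One signature per mappable class (9 vegetation formations of the packaged
#' Taibai MAB table, cultivated plants, non-vegetation) plus parent
#' signatures used to synthesize the two mixed-forest classes as pixel-level
#' 50/50 mixtures. Values are winter-image digital numbers (DN) for the four
#' bands Blue, Green, Red, NIR.
#'
#' Construction constraints, all checked by [validate_signatures()]:
#' * every vegetation class has NIR > Red;
#' * the non-vegetation signature has NDVI x 100 below -2 (it is the class
#'   the layer-1 fuzzy membership rule must catch);
#' * coniferous signatures (*Pinus armandii*, *Abies fargesii*,
#'   *Larix chinensis*) have the highest NIR means and carry a
#'   high-frequency multiplicative texture so GLCM features discriminate
#'   them (conifers are brighter and more textured than broad-leaved
#'   forests in winter imagery).
#'
#' @return data.frame with columns `class`, `role` ("class"/"parent"),
#'   `blue`, `green`, `red`, `nir`, `sd`, `texture`, `mix_a`, `mix_b`.
#' @export
default_signatures <- function() {
  sig <- function(class, role, b, g, r, n, sd = 6, texture = FALSE,
                  mix_a = NA_character_, mix_b = NA_character_) {
    data.frame(class = class, role = role, blue = b, green = g, red = r,
               nir = n, sd = sd, texture = texture, mix_a = mix_a,
               mix_b = mix_b, stringsAsFactors = FALSE)
  }
  bet <- "Betula albosinensis"
  bsub <- "Betula albosinensis (subalpine form)"
  bsep <- "Betula albosinensis var. septentrionalis forest"
  rbind(
    sig("Cultivated plants", "class", 45, 60, 55, 95),
    sig("Quercus variabilis forest", "class", 30, 45, 40, 105),
    sig("Quercus aliena var. acuteserrata forest", "class", 32, 50, 45, 122),
    sig("Quercus liaotungensis forest", "class", 28, 42, 38, 140),
    sig("mixed forests of Betula albosinensis with Pinus armandii", "class",
        NA, NA, NA, NA, mix_a = bet, mix_b = "Pinus armandii"),
    sig(bsep, "class", 35, 55, 48, 152),
    sig(paste("mixed forests of Betula albosinensis with",
              "Betula albosinensis var. septentrionalis"), "class",
        NA, NA, NA, NA, mix_a = bsub, mix_b = bsep),
    sig("Abies fargesii forest", "class", 22, 35, 28, 200, texture = TRUE),
    sig("Larix chinensis forest", "class", 26, 40, 34, 172, texture = TRUE),
    sig("subalpine shrub and meadow", "class", 50, 70, 62, 130),
    sig("Non-vegetation", "class", 95, 105, 115, 110),
    sig(bet, "parent", 38, 58, 50, 135),
    # synthetic stand-in: the birch component of the subalpine mixed stand
    # gets its own signature so no parent is shared across mixture classes
    # (a shared parent would make the noiseless scene non-separable)
    sig(bsub, "parent", 30, 50, 42, 146),
    sig("Pinus armandii", "parent", 25, 38, 30, 185, texture = TRUE)
  )
}

bands_ <- c("blue", "green", "red", "nir")

#' Validate a signature table
#'
#' Checks the invariants documented in [default_signatures()].
#' @param signatures signature data.frame.
#' @return the table, invisibly; errors describe the offending class.
#' @export
validate_signatures <- function(signatures) {
  stopifnot(is.data.frame(signatures),
            all(c("class", "role", bands_, "sd") %in% names(signatures)))
  eff <- effective_means_(signatures)
  if (any(eff[, bands_] < 0, na.rm = TRUE)) stop("band means must be >= 0")
  veg <- eff$class != "Non-vegetation"
  if (any(eff$nir[veg] <= eff$red[veg])) {
    stop("vegetation signature with NIR <= Red: ",
         paste(eff$class[veg][eff$nir[veg] <= eff$red[veg]], collapse = ", "))
  }
  nv <- eff[eff$class == "Non-vegetation", ]
  if (nrow(nv) == 1L) {
    ndvi100 <- 100 * (nv$nir - nv$red) / (nv$nir + nv$red)
    if (ndvi100 >= -2) stop("non-vegetation signature must have NDVI*100 < -2")
  }
  invisible(signatures)
}

# expected band means per class, resolving 50/50 mixtures to their average
effective_means_ <- function(signatures) {
  cls <- signatures[signatures$role == "class", , drop = FALSE]
  for (i in seq_len(nrow(cls))) {
    if (!is.na(cls$mix_a[i])) {
      a <- signatures[signatures$class == cls$mix_a[i], ][1L, ]
      b <- signatures[signatures$class == cls$mix_b[i], ][1L, ]
      if (nrow(a) == 0L || nrow(b) == 0L) {
        stop("mixture parents missing for class ", cls$class[i])
      }
      cls[i, bands_] <- (a[, bands_] + b[, bands_]) / 2
    }
  }
  cls
}

#' Synthetic digital surface model (DSM)
#'
#' An east-west ridge at `ridge_row` (1-based row index) with elevation
#' falling off linearly toward `base_elev` away from the ridge, modulated by
#' a smooth seeded multiplicative perturbation. The maximum elevation equals
#' `peak_elev` exactly, attained on the ridge row; with
#' `perturb_amp = 0` every column is strictly decreasing away from the ridge.
#'
#' @param rows,cols raster dimensions (pixels).
#' @param base_elev,peak_elev metres; `peak_elev > base_elev`.
#' @param ridge_row 1-based ridge row; default the middle row.
#' @param perturb_amp relative amplitude of the smooth perturbation in
#'   `[0, 1)`; default 0.15.
#' @param seed integer seed.
#' @return numeric matrix `rows x cols` of elevations (metres).
#' @export
synth_dsm <- function(rows, cols, base_elev = 500, peak_elev = 3771.2,
                      ridge_row = NULL, perturb_amp = 0.15, seed = 1L) {
  if (rows < 1 || cols < 1) stop("raster dimensions must be positive")
  stopifnot(peak_elev > base_elev, perturb_amp >= 0, perturb_amp < 1)
  if (is.null(ridge_row)) ridge_row <- max(1L, floor(rows / 2))
  if (ridge_row < 1 || ridge_row > rows) stop("ridge_row outside raster")
  with_seed_(seed, {
    r <- matrix(seq_len(rows), rows, cols)
    c_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    maxd <- max(ridge_row - 1L, rows - ridge_row, 1L)
    d <- abs(r - ridge_row) / maxd
    g <- 1
    if (perturb_amp > 0) {
      ph <- runif(4, 0, 2 * pi)
      fr <- runif(4, 1.5, 4)
      s <- (sin(2 * pi * fr[1] * r / rows + ph[1]) *
              sin(2 * pi * fr[2] * c_ / cols + ph[2]) +
            sin(2 * pi * fr[3] * r / rows + ph[3]) *
              sin(2 * pi * fr[4] * c_ / cols + ph[4])) / 2
      g <- 1 + perturb_amp * s
    }
    peak_elev - (peak_elev - base_elev) * d * g
  })
}

#' Synthetic ground-truth label raster
#'
#' Labels each pixel with the class of the belt containing its (noisy)
#' elevation: rows at or above `ridge_row` are the north slope, rows below
#' are the south slope, and a per-pixel elevation jitter
#' `N(0, boundary_sigma)` fuzzes the belt boundaries. Basal-zone pixels are
#' split into cultivated plants and non-vegetation patches (smooth random
#' field thresholded at `nonveg_frac`). Pixels whose belt lookup fails (above
#' the table summit) become `NA`.
#'
#' @param dsm elevation matrix from [synth_dsm()].
#' @param ridge_row 1-based ridge row used for the slope split.
#' @param table a [mab_table].
#' @param boundary_sigma metres of boundary fuzz (>= 0).
#' @param nonveg_frac fraction of Basal-zone pixels labelled non-vegetation.
#' @param seed integer seed.
#' @return list with `labels` (integer matrix, codes into `legend`),
#'   `legend` (data.frame `id`, `class`).
#' @export
synth_truth <- function(dsm, ridge_row, table = load_mab_table(),
                        boundary_sigma = 50, nonveg_frac = 0.3, seed = 1L) {
  stopifnot(is.matrix(dsm), boundary_sigma >= 0,
            nonveg_frac >= 0, nonveg_frac <= 1)
  rows <- nrow(dsm); cols <- ncol(dsm)
  with_seed_(seed, {
    eps <- if (boundary_sigma > 0) {
      matrix(rnorm(rows * cols, 0, boundary_sigma), rows, cols)
    } else 0
    # boundary fuzz is clamped into the table's altitude span so only the
    # DSM itself (not the jitter) can push a pixel into no-data
    top <- max(table$alt_hi)
    alt <- pmin(pmax(dsm + eps, 0), top)
    alt[dsm > top] <- dsm[dsm > top]
    north <- row(dsm) <= ridge_row
    belt <- matrix(NA_integer_, rows, cols)
    belt[north] <- belt_at_vec_(table, "north", alt[north])
    belt[!north] <- belt_at_vec_(table, "south", alt[!north])

    legend <- scene_legend_(table)
    labels <- matrix(NA_integer_, rows, cols)
    ok <- !is.na(belt)
    formation <- table$formation[belt[ok]]
    lab <- match(formation, legend$class)
    labels[ok] <- lab

    basal <- matrix(FALSE, rows, cols)
    basal[ok] <- is_basal_(table$formation)[belt[ok]]
    if (any(basal)) {
      # spatially coherent non-vegetation patches inside the basal zone
      # smooth field only: per-pixel noise would speckle the basal zone with
      # single-pixel patches no object-based layer-1 classification can mask
      ph <- runif(4, 0, 2 * pi)
      u <- sin(2 * pi * 6 * row(dsm) / rows + ph[1]) +
        sin(2 * pi * 6 * col(dsm) / cols + ph[2]) +
        0.6 * sin(2 * pi * 13 * row(dsm) / rows + ph[3]) *
          sin(2 * pi * 11 * col(dsm) / cols + ph[4])
      thr <- stats::quantile(u[basal], probs = nonveg_frac)
      nonveg <- basal & u <= thr
      labels[basal] <- match("Cultivated plants", legend$class)
      labels[nonveg] <- match("Non-vegetation", legend$class)
    }
    list(labels = labels, legend = legend)
  })
}

# canonical class legend for a MAB table: formations in belt order
# (north first), then cultivated plants and non-vegetation
scene_legend_ <- function(table) {
  f <- unique(table$formation[!is_basal_(table$formation)])
  classes <- c(f, "Cultivated plants", "Non-vegetation")
  data.frame(id = seq_along(classes), class = classes,
             stringsAsFactors = FALSE)
}

#' Synthetic 4-band image from a truth raster
#'
#' Pixel values are the class signature band means plus independent Gaussian
#' noise (`sd * sd_scale`), clipped at 0. Mixed-forest classes draw each
#' pixel's parent signature with probability 1/2, so mixed objects are
#' genuine pixel-level mixtures. Textured (coniferous) signatures are
#' modulated by a seeded high-frequency multiplicative pattern of relative
#' amplitude `texture_amp`.
#'
#' @param truth result of [synth_truth()].
#' @param signatures signature table (see [default_signatures()]).
#' @param seed integer seed.
#' @param sd_scale multiplier on the per-signature noise sd (0 = noiseless).
#' @param texture_amp relative texture amplitude (default 0.08).
#' @return numeric array `rows x cols x 4` with band dimnames
#'   `blue, green, red, nir`; `NA` where truth is `NA`.
#' @export
synth_image <- function(truth, signatures = default_signatures(), seed = 1L,
                        sd_scale = 1, texture_amp = 0.08) {
  validate_signatures(signatures)
  labels <- truth$labels
  legend <- truth$legend
  rows <- nrow(labels); cols <- ncol(labels)
  present <- sort(unique(labels[!is.na(labels)]))
  have <- legend$class[present] %in%
    signatures$class[signatures$role == "class"]
  if (!all(have)) {
    stop("missing signature for label: ",
         paste(legend$class[present][!have], collapse = ", "))
  }
  with_seed_(seed, {
    img <- array(NA_real_, c(rows, cols, 4),
                 dimnames = list(NULL, NULL, bands_))
    tex <- {
      ph <- runif(2, 0, 2 * pi)
      1 + texture_amp * sin(2.7 * row(labels) + ph[1]) *
        sin(3.1 * col(labels) + ph[2])
    }
    for (id in present) {
      cl <- legend$class[id]
      s <- signatures[signatures$class == cl & signatures$role == "class", ]
      pix <- which(labels == id)
      npx <- length(pix)
      if (is.na(s$mix_a)) {
        mean_mat <- matrix(unlist(s[, bands_]), npx, 4, byrow = TRUE)
        textured <- rep(isTRUE(s$texture), npx)
      } else {
        a <- signatures[signatures$class == s$mix_a, ][1L, ]
        b <- signatures[signatures$class == s$mix_b, ][1L, ]
        pick_b <- runif(npx) < 0.5
        mean_mat <- matrix(unlist(a[, bands_]), npx, 4, byrow = TRUE)
        mean_mat[pick_b, ] <- matrix(unlist(b[, bands_]), sum(pick_b), 4,
                                     byrow = TRUE)
        textured <- ifelse(pick_b, isTRUE(b$texture), isTRUE(a$texture))
      }
      mean_mat[textured, ] <- mean_mat[textured, , drop = FALSE] * tex[pix][textured]
      noise <- if (s$sd * sd_scale > 0) {
        matrix(rnorm(npx * 4, 0, s$sd * sd_scale), npx, 4)
      } else 0
      vals <- pmax(mean_mat + noise, 0)
      for (bdx in 1:4) {
        band <- img[, , bdx]
        band[pix] <- vals[, bdx]
        img[, , bdx] <- band
      }
    }
    img
  })
}

#' Generate a complete synthetic mountain scene
#'
#' Bundles [synth_dsm()], [synth_truth()] and [synth_image()] into one seeded
#' scene: DSM, 4-band image, ground-truth labels, legend and the generator
#' parameters. Identical parameters and seed give a bit-identical bundle.
#'
#' @param rows,cols scene size in pixels (default 512 x 512 at a nominal
#'   10 m pixel).
#' @param base_elev,peak_elev,ridge_row,perturb_amp see [synth_dsm()].
#' @param boundary_sigma,nonveg_frac see [synth_truth()].
#' @param sd_scale,texture_amp see [synth_image()].
#' @param table a [mab_table].
#' @param signatures signature table.
#' @param seed master seed; stage seeds are derived as `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return A `scene_bundle` list: `dsm`, `image`, `truth`, `legend`,
#'   `ridge_row`, `params`.
#' @export
synth_scene <- function(rows = 512L, cols = 512L, base_elev = 500,
                        peak_elev = 3771.2, ridge_row = NULL,
                        perturb_amp = 0.15, boundary_sigma = 50,
                        nonveg_frac = 0.3, sd_scale = 1, texture_amp = 0.08,
                        table = load_mab_table(),
                        signatures = default_signatures(), seed = 1L) {
  if (is.null(ridge_row)) ridge_row <- max(1L, floor(rows / 2))
  dsm <- synth_dsm(rows, cols, base_elev, peak_elev, ridge_row, perturb_amp,
                   seed = seed)
  truth <- synth_truth(dsm, ridge_row, table, boundary_sigma, nonveg_frac,
                       seed = seed + 1L)
  image <- synth_image(truth, signatures, seed = seed + 2L,
                       sd_scale = sd_scale, texture_amp = texture_amp)
  structure(list(dsm = dsm, image = image, truth = truth$labels,
                 legend = truth$legend, ridge_row = ridge_row,
                 table = table, signatures = signatures,
                 params = list(rows = rows, cols = cols,
                               base_elev = base_elev, peak_elev = peak_elev,
                               ridge_row = ridge_row,
                               perturb_amp = perturb_amp,
                               boundary_sigma = boundary_sigma,
                               nonveg_frac = nonveg_frac,
                               sd_scale = sd_scale,
                               texture_amp = texture_amp, seed = seed)),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat("synthetic scene:", nrow(x$dsm), "x", ncol(x$dsm), "px, elevation",
      round(min(x$dsm)), "-", round(max(x$dsm)), "m, seed",
      x$params$seed, "\n")
  tab <- table(x$legend$class[x$truth])
  print(tab)
  invisible(x)
}

#' Clustering-feature prototypes implied by a signature table
#'
#' The automatic sample selector compares cluster centroids with a per-class
#' prototype in the clustering feature space (band means, brightness, NDVI,
#' DVI, RVI, Max.Diff). For synthetic scenes the prototypes are the expected
#' feature values computed from the spectral signatures; for real imagery a
#' user-supplied table of the same shape plays this role.
#'
#' @param signatures signature table.
#' @return data.frame: one row per pure class and one row per parent for the
#'   mixed-forest classes (their object-level features are bimodal at the
#'   parents, not at the 50/50 blend), columns
#'   `mean_blue..mean_nir, brightness, ndvi, dvi, rvi, max_diff`, with
#'   `class` as a column. Multi-row prototypes are matched by minimum
#'   distance over rows.
#' @export
prototypes_from_signatures <- function(signatures = default_signatures()) {
  cls <- signatures[signatures$role == "class", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    if (is.na(cls$mix_a[i])) {
      r <- cls[i, c("class", bands_)]
    } else {
      a <- signatures[signatures$class == cls$mix_a[i], ][1L, ]
      b <- signatures[signatures$class == cls$mix_b[i], ][1L, ]
      r <- rbind(a[, c("class", bands_)], b[, c("class", bands_)])
      r$class <- cls$class[i]
    }
    rows[[i]] <- r
  }
  eff <- do.call(rbind, rows)
  m <- as.matrix(eff[, bands_])
  brightness <- rowMeans(m)
  ndvi <- (m[, "nir"] - m[, "red"]) / (m[, "nir"] + m[, "red"])
  dvi <- m[, "nir"] - m[, "red"]
  rvi <- m[, "nir"] / m[, "red"]
  max_diff <- apply(m, 1, function(v) max(abs(outer(v, v, "-")))) / brightness
  data.frame(class = eff$class, mean_blue = m[, "blue"],
             mean_green = m[, "green"], mean_red = m[, "red"],
             mean_nir = m[, "nir"], brightness = brightness, ndvi = ndvi,
             dvi = dvi, rvi = rvi, max_diff = max_diff,
             stringsAsFactors = FALSE)
}
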