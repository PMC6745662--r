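#' Configuration for a synthetic fragmented landscape
#'
#' Parameters of the synthetic landscape generator, which emulates a dry
#' woodland landscape fragmented by pasture: circular woodland patches on a
#' regular raster grid, with canopy cover and Landsat-like red/near-infrared
#' reflectance bands such that NDVI is high inside woodland and low in
#' pasture.
#'
#' @param grid_size cells per side of the (square) raster.
#' @param resolution cell size in meters (default 30, Landsat-like).
#' @param n_patches number of circular woodland patches (0 allowed).
#' @param patch_radius_range numeric length-2, patch radii in meters.
#' @param canopy_range numeric length-2, percent canopy cover range inside
#'   woodland (0-100).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(grid_size = 200, resolution = 30, n_patches = 6,
                             patch_radius_range = c(150, 450),
                             canopy_range = c(40, 90), seed = 1) {
  if (!is.numeric(grid_size) || grid_size <= 0)
    stopf("grid_size must be a positive integer")
  if (!is.numeric(resolution) || resolution <= 0)
    stopf("resolution must be > 0")
  if (n_patches < 0) stopf("n_patches must be >= 0")
  if (any(canopy_range < 0) || any(canopy_range > 100))
    stopf("canopy_range must lie in [0, 100]")
  structure(list(
    grid_size = as.integer(grid_size), resolution = resolution,
    n_patches = as.integer(n_patches),
    patch_radius_range = patch_radius_range,
    canopy_range = canopy_range, seed = as.integer(seed)
  ), class = "landscape_config")
}

#' Aligned raster grid stack
#'
#' Lightweight container for a stack of aligned single-band grids sharing one
#' origin and resolution. Layer matrices are indexed `m[i, j]` with `i` the
#' x (easting) cell index and `j` the y (northing) cell index; cell `(i, j)`
#' covers `[origin + (i-1) * res, origin + i * res)` in x and likewise in y,
#' with its center at `origin + (i - 0.5) * res`.
#'
#' @param layers named list of equal-dimension numeric matrices.
#' @param origin numeric length-2: x and y of the lower-left corner (meters).
#' @param resolution meters per cell.
#' @return an object of class `landscape_raster`.
#' @export
landscape_raster <- function(layers, origin = c(0, 0), resolution = 30) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("all layers must share the same shape")
  if (resolution <= 0) stopf("resolution must be > 0")
  structure(list(
    origin = as.numeric(origin), resolution = resolution,
    nx = dims[1, 1], ny = dims[2, 1], layers = layers
  ), class = "landscape_raster")
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("<landscape_raster> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$resolution, x$origin[1], x$origin[2]))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# containing-cell indices for point coordinates; NA outside the extent
cell_index <- function(raster, x, y) {
  i <- floor((x - raster$origin[1]) / raster$resolution) + 1
  j <- floor((y - raster$origin[2]) / raster$resolution) + 1
  bad <- is.na(i) | is.na(j) | i < 1 | i > raster$nx | j < 1 | j > raster$ny
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

# centers of cells (i, j) in map coordinates
cell_center <- function(raster, i, j) {
  cbind(x = raster$origin[1] + (i - 0.5) * raster$resolution,
        y = raster$origin[2] + (j - 0.5) * raster$resolution)
}

#' Sample raster layer values at point locations
#'
#' Nearest-cell (containing-cell) sampling with no interpolation, so that
#' categorical and continuous layers are sampled consistently.
#'
#' @param raster a [landscape_raster()].
#' @param layer layer name.
#' @param x,y point coordinates in map units.
#' @return numeric vector of sampled values; `NA` outside the extent.
#' @export
raster_extract <- function(raster, layer, x, y) {
  if (!layer %in% names(raster$layers))
    stopf("no layer named '%s'", layer)
  ij <- cell_index(raster, x, y)
  m <- raster$layers[[layer]]
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ij[, 1])
  out[ok] <- m[ij[ok, , drop = FALSE]]
  out
}

# bilinear upsampling of a coarse random field to an nx x ny grid; used to
# give canopy/reflectance layers smooth spatial structure
smooth_field <- function(nx, ny, coarse = 8) {
  g <- matrix(runif((coarse + 2)^2), coarse + 2, coarse + 2)
  fx <- seq(1, coarse + 2, length.out = nx)
  fy <- seq(1, coarse + 2, length.out = ny)
  ix <- pmin(floor(fx), coarse + 1); tx <- fx - ix
  iy <- pmin(floor(fy), coarse + 1); ty <- fy - iy
  # separable bilinear interpolation
  a <- g[ix, iy] * outer(1 - tx, 1 - ty) + g[ix + 1, iy] * outer(tx, 1 - ty) +
    g[ix, iy + 1] * outer(1 - tx, ty) + g[ix + 1, iy + 1] * outer(tx, ty)
  a
}

#' Simulate a fragmented woodland landscape
#'
#' Generates aligned raster layers for a synthetic landscape: a binary
#' woodland mask (union of circular patches), percent canopy cover (smooth
#' field, high inside woodland, near zero in pasture), and red/near-infrared
#' reflectance bands constructed so NDVI is high inside woodland and low
#' outside. Deterministic given `config$seed`.
#'
#' @param config a [landscape_config()].
#' @return a [landscape_raster()] with layers `woodland_mask`, `canopy_pct`,
#'   `red`, `nir`, plus a logical element `no_woodland` flagging the
#'   degenerate empty-mask case (`n_patches = 0` or no patch intersecting the
#'   grid).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  n <- config$grid_size
  res <- config$resolution
  ext <- n * res
  with_seed(config$seed, {
    mask <- matrix(0, n, n)
    if (config$n_patches > 0) {
      cx <- runif(config$n_patches, 0.1 * ext, 0.9 * ext)
      cy <- runif(config$n_patches, 0.1 * ext, 0.9 * ext)
      r <- runif(config$n_patches, config$patch_radius_range[1],
                 config$patch_radius_range[2])
      centers_x <- (seq_len(n) - 0.5) * res
      centers_y <- (seq_len(n) - 0.5) * res
      for (p in seq_len(config$n_patches)) {
        dx2 <- (centers_x - cx[p])^2
        dy2 <- (centers_y - cy[p])^2
        mask[outer(dx2, dy2, "+") <= r[p]^2] <- 1
      }
    }
    f_can <- smooth_field(n, n)
    f_ndvi <- smooth_field(n, n)
    f_red <- smooth_field(n, n)
    canopy <- ifelse(mask > 0,
                     config$canopy_range[1] +
                       diff(config$canopy_range) * f_can,
                     5 * f_can)
    canopy <- pmin(pmax(canopy, 0), 100)
    ndvi_t <- ifelse(mask > 0, 0.55 + 0.3 * f_ndvi, 0.05 + 0.15 * f_ndvi)
    red <- 0.12 + 0.06 * f_red
    nir <- red * (1 + ndvi_t) / (1 - ndvi_t)
    out <- landscape_raster(
      list(woodland_mask = mask, canopy_pct = canopy, red = red, nir = nir),
      origin = c(0, 0), resolution = res
    )
    out$no_woodland <- all(mask == 0)
    out
  })
}

#' Derive habitat covariate layers
#'
#' Adds the covariate layers used by the transition model to a landscape:
#' NDVI from the red/NIR bands, K-means vegetation-density classes on NDVI
#' (class index increasing with density), and Euclidean distance to the
#' nearest woodland cell (meters, 0 inside woodland).
#'
#' @param raster a [landscape_raster()] with layers `red`, `nir`,
#'   `woodland_mask`.
#' @param K number of vegetation-density classes.
#' @param seed seed for the K-means classification.
#' @return the raster with layers `ndvi`, `veg_class`, `dist_edge` added (and
#'   attribute-like element `veg_class_means`).
#' @export
derive_covariate_layers <- function(raster, K = 10, seed = 1) {
  stopifnot(inherits(raster, "landscape_raster"))
  nd <- ndvi(raster$layers$red, raster$layers$nir)
  km <- kmeans_classify(nd, K = K, seed = seed)
  raster$layers$ndvi <- nd
  raster$layers$veg_class <- km$veg_class
  raster$veg_class_means <- km$class_means
  if (all(raster$layers$woodland_mask == 0)) {
    warnf("landscape has no woodland; dist_edge layer set to NA")
    raster$layers$dist_edge <- matrix(NA_real_, raster$nx, raster$ny)
  } else {
    raster$layers$dist_edge <- distance_to_edge(raster)
  }
  raster
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/...`
#' header followed by rows of values from the top row down).
#'
#' @param file path.
#' @param raster a [landscape_raster()] (write).
#' @param layer layer name to write.
#' @param nodata value standing in for `NA` on disk.
#' @return for `read_ascii_grid`, a [landscape_raster()] with one layer named
#'   `layer`.
#' @export
write_ascii_grid <- function(raster, layer, file, nodata = -9999) {
  m <- raster$layers[[layer]]
  if (is.null(m)) stopf("no layer named '%s'", layer)
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", raster$nx), sprintf("nrows %d", raster$ny),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$resolution),
    sprintf("NODATA_value %.10g", nodata)
  )
  # ASCII grids store the top (max y) row first; our matrices are [x, y]
  rows <- vapply(rev(seq_len(raster$ny)), function(j)
    paste(format(m[, j], trim = TRUE, digits = 10), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(file, layer = "band1") {
  lines <- readLines(file)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)  # file rows: top-down
  m <- t(m[rev(seq_len(ny)), , drop = FALSE])  # back to [x, y], y up
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  org <- c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0)
  landscape_raster(setNames(list(m), layer), origin = org,
                   resolution = hdr$cellsize)
}
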