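#' Normalized Difference Vegetation Index
#'
#' Cellwise `(nir - red) / (nir + red)`; cells where `nir + red = 0` are
#' undefined and set to `NA`. Values are bounded in `[-1, 1]` wherever
#' defined; higher values indicate denser green vegetation.
#'
#' @param red,nir reflectance grids (equal-shape matrices, values >= 0).
#' @return matrix of NDVI values.
#' @export
ndvi <- function(red, nir) {
  if (!all(dim(red) == dim(nir))) stopf("red and nir shapes differ")
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stopf("reflectance values must be >= 0")
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Unsupervised vegetation-density classes from NDVI
#'
#' One-dimensional K-means on the non-missing NDVI values (via
#' [stats::kmeans()]), with classes relabeled in increasing order of cluster
#' mean so that a higher class index always means denser vegetation.
#' Deterministic given `seed`; `NA` cells stay `NA`.
#'
#' @param ndvi NDVI grid (matrix) or numeric vector.
#' @param K number of classes (>= 2).
#' @param seed integer seed.
#' @return list with `veg_class` (same shape as input, integer classes
#'   `0..K-1`) and `class_means` (increasing numeric vector of length K).
#' @export
kmeans_classify <- function(ndvi, K = 10, seed = 1) {
  if (K < 2) stopf("K must be >= 2")
  vals <- as.numeric(ndvi)
  ok <- !is.na(vals)
  if (length(unique(vals[ok])) < K)
    stopf("K = %d exceeds the number of distinct non-missing values", K)
  km <- with_seed(seed,
    kmeans(vals[ok], centers = K, nstart = 10, iter.max = 100))
  ord <- order(km$centers)
  relabel <- integer(K)
  relabel[ord] <- seq_len(K) - 1L   # 0-based, increasing with density
  cls <- rep(NA_integer_, length(vals))
  cls[ok] <- relabel[km$cluster]
  if (is.matrix(ndvi)) cls <- matrix(cls, nrow(ndvi), ncol(ndvi))
  list(veg_class = cls, class_means = as.numeric(km$centers)[ord])
}

#' Euclidean distance to the nearest woodland cell
#'
#' For the grid form, computes the exact Euclidean distance transform on
#' cell centers (0 on woodland cells, meters elsewhere). For the point form,
#' returns 0 for points whose containing cell is woodland and otherwise the
#' exact distance to the nearest woodland cell center.
#'
#' @param raster a [landscape_raster()] containing a `woodland_mask` layer
#'   (binary) -- or, if `mask` is given, any raster supplying the geometry.
#' @param points optional data.frame/matrix with columns `x`, `y`; if given,
#'   distances are returned for these points instead of the whole grid.
#' @param mask optional binary matrix overriding the `woodland_mask` layer.
#' @return matrix of distances in meters (grid form) or numeric vector
#'   (point form).
#' @export
distance_to_edge <- function(raster, points = NULL, mask = NULL) {
  m <- mask %||% raster$layers$woodland_mask
  if (is.null(m)) stopf("raster has no woodland_mask layer")
  if (all(m == 0)) stopf("woodland mask is empty")
  if (is.null(points)) {
    return(sqrt(C_edt_sq(m)) * raster$resolution)
  }
  px <- points[, "x"]
  py <- points[, "y"]
  wood <- which(m != 0, arr.ind = TRUE)
  wc <- cell_center(raster, wood[, 1], wood[, 2])
  ij <- cell_index(raster, px, py)
  out <- numeric(length(px))
  for (k in seq_along(px)) {
    if (!is.na(ij[k, 1]) && m[ij[k, 1], ij[k, 2]] != 0) {
      out[k] <- 0
    } else {
      out[k] <- sqrt(min((wc[, 1] - px[k])^2 + (wc[, 2] - py[k])^2))
    }
  }
  out
}

#' Attach per-slot habitat covariates to tracks
#'
#' Samples the named raster layers at each present position by
#' containing-cell lookup (no interpolation, so categorical and continuous
#' layers stay consistent). Slots with missing positions get missing
#' covariates; positions outside the raster extent get `NA` with a warning.
#'
#' @param tracks a `track_set` (see [build_tracks()]).
#' @param raster a [landscape_raster()].
#' @param layers character vector of layer names to attach.
#' @return `tracks` with one column per requested layer.
#' @export
attach_covariates <- function(tracks, raster,
                              layers = c("veg_class", "canopy_pct",
                                         "dist_edge")) {
  missing_layers <- setdiff(layers, names(raster$layers))
  if (length(missing_layers) > 0)
    stopf("raster lacks layer(s): %s", paste(missing_layers, collapse = ", "))
  present <- !is.na(tracks$x) & !is.na(tracks$y)
  outside <- present &
    is.na(cell_index(raster, tracks$x, tracks$y)[, 1])
  if (any(outside))
    warnf("%d position(s) outside the raster extent; covariates set to NA",
          sum(outside))
  for (ly in layers) {
    v <- rep(NA_real_, nrow(tracks))
    v[present] <- raster_extract(raster, ly, tracks$x[present],
                                 tracks$y[present])
    tracks[[ly]] <- v
  }
  tracks
}

#' Build a covariate design for the transition model
#'
#' Assembles the design matrix entering the multinomial-logit transition
#' model: an intercept column first, numeric covariates (optionally
#' z-standardized, with the training mean/sd stored for reuse at prediction
#' time), and categorical covariates expanded to K-1 indicator columns
#' against a reference level. Categorical levels observed on fewer than
#' `merge_rare` slots are merged into the nearest level by numeric label
#' (vegetation-density classes are ordinal), preventing unidentifiable
#' coefficients. Slots with any missing covariate are flagged and receive
#' the reference row (intercept only).
#'
#' @param tracks a `track_set` carrying the covariate columns.
#' @param numeric character vector of numeric covariate columns.
#' @param categorical character vector of categorical covariate columns.
#' @param reference named list of reference levels (default: first sorted
#'   level of each categorical).
#' @param standardize z-standardize numeric covariates?
#' @param merge_rare minimum slot count for a categorical level to keep its
#'   own indicator (set 0 to disable merging).
#' @return an object of class `covariate_design` with elements `X` (the
#'   n x (1+p) design matrix), `na_row` (logical flag per row), and the
#'   metadata needed to rebuild rows for new data ([design_matrix()],
#'   [design_row()]).
#' @export
build_design <- function(tracks, numeric = character(),
                         categorical = character(), reference = list(),
                         standardize = TRUE, merge_rare = 50) {
  for (v in c(numeric, categorical))
    if (!v %in% names(tracks)) stopf("covariate '%s' not found in tracks", v)
  n <- nrow(tracks)
  des <- list(numeric = numeric, categorical = categorical,
              standardize = standardize, center = c(), scale = c(),
              range = list(), levels = list(), merge_map = list(),
              reference = list())

  cols <- list(`(Intercept)` = rep(1, n))
  na_row <- rep(FALSE, n)

  for (v in numeric) {
    val <- as.numeric(tracks[[v]])
    na_row <- na_row | is.na(val)
    m <- mean(val, na.rm = TRUE)
    s <- sd(val, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stopf("numeric covariate '%s' is constant", v)
    des$range[[v]] <- range(val, na.rm = TRUE)
    if (standardize) {
      des$center[v] <- m; des$scale[v] <- s
      val <- (val - m) / s
    } else {
      des$center[v] <- 0; des$scale[v] <- 1
    }
    val[is.na(val)] <- 0  # reference (training mean) for flagged rows
    cols[[v]] <- val
  }

  for (v in categorical) {
    val <- as.character(tracks[[v]])
    na_row <- na_row | is.na(val)
    cnt <- table(val[!is.na(val)])
    lv <- names(cnt)
    map <- setNames(lv, lv)
    if (merge_rare > 0 && length(lv) > 1) {
      num_lv <- suppressWarnings(as.numeric(lv))
      if (!anyNA(num_lv)) {
        repeat {
          kept <- unique(map)
          cnt2 <- sapply(kept, function(k) sum(cnt[names(map)[map == k]]))
          rare <- kept[cnt2 < merge_rare]
          if (length(rare) == 0 || length(kept) == 1) break
          r <- rare[which.min(cnt2[match(rare, kept)])]
          others <- setdiff(kept, r)
          tgt <- others[which.min(abs(as.numeric(others) - as.numeric(r)))]
          map[map == r] <- tgt
        }
      }
    }
    val_m <- ifelse(is.na(val), NA, map[val])
    lev <- sort(unique(map))
    ref <- reference[[v]] %||% lev[1]
    if (!ref %in% lev) stopf("reference level '%s' not among levels of '%s'",
                             ref, v)
    des$levels[[v]] <- lev
    des$merge_map[[v]] <- map
    des$reference[[v]] <- ref
    for (L in setdiff(lev, ref)) {
      d <- as.numeric(!is.na(val_m) & val_m == L)
      d[is.na(val_m)] <- 0
      cols[[paste0(v, L)]] <- d
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ok <- !na_row
  if (sum(ok) > 0 && qr(X[ok, , drop = FALSE])$rank < ncol(X))
    stopf("design matrix is rank-deficient on the training slots")
  des$colnames <- colnames(X)
  des$X <- X
  des$na_row <- na_row
  class(des) <- "covariate_design"
  des
}

#' Rebuild a design matrix for new tracks
#'
#' @param design a `covariate_design` from [build_design()].
#' @param tracks new track data carrying the same covariate columns.
#' @return design matrix with the stored standardization and dummy coding;
#'   an unseen categorical level raises an error naming the level.
#' @export
design_matrix <- function(design, tracks) {
  n <- nrow(tracks)
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in design$numeric) {
    val <- (as.numeric(tracks[[v]]) - design$center[v]) / design$scale[v]
    val[is.na(val)] <- 0
    cols[[v]] <- val
  }
  for (v in design$categorical) {
    val <- as.character(tracks[[v]])
    known <- is.na(val) | val %in% names(design$merge_map[[v]])
    if (!all(known))
      stopf("unseen level '%s' of covariate '%s'",
            unique(val[!known])[1], v)
    val_m <- ifelse(is.na(val), NA, design$merge_map[[v]][val])
    for (L in setdiff(design$levels[[v]], design$reference[[v]])) {
      d <- as.numeric(!is.na(val_m) & val_m == L)
      cols[[paste0(v, L)]] <- d
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- design$colnames
  X
}

# one design row from a named list of raw-scale covariate values; numeric
# covariates omitted are held at the training mean, categoricals at the
# reference level
design_row <- function(design, values = list()) {
  row <- c(`(Intercept)` = 1)
  for (v in design$numeric) {
    raw <- values[[v]]
    row[v] <- if (is.null(raw)) 0
              else (raw - design$center[v]) / design$scale[v]
  }
  for (v in design$categorical) {
    L0 <- values[[v]] %||% design$reference[[v]]
    if (!L0 %in% names(design$merge_map[[v]]))
      stopf("unseen level '%s' of covariate '%s'", L0, v)
    L0 <- design$merge_map[[v]][L0]
    for (L in setdiff(design$levels[[v]], design$reference[[v]]))
      row[paste0(v, L)] <- as.numeric(L0 == L)
  }
  row[design$colnames]
}
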