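#' Parameters of the proximity-to-impervious-area decay
#'
#' The PIA covariate re-expresses the Euclidean distance `d` (in degrees) to
#' the nearest impervious pixel as `exp(-d / sigma_u)`, with the nearest-
#' neighbour search truncated at `search_radius`; beyond the radius PIA is
#' defined as zero. The shipped default `sigma_u = 0.28` degrees is the
#' value estimated from the original continental survey; see
#' [estimate_sigma_u()] to recompute it for other data.
#'
#' @param sigma_u Decay scale in degrees (> 0).
#' @param search_radius Truncation radius in degrees (> 0), default 1.
#' @return An object of class `pia_params`.
#' @export
pia_params <- function(sigma_u = 0.28, search_radius = 1.0) {
  stopifnot(sigma_u > 0, search_radius > 0)
  structure(list(sigma_u = sigma_u, search_radius = search_radius),
            class = "pia_params")
}

# integral nesting factor of a high-res grid inside a coarse grid, or error
nesting_factor <- function(hr, coarse) {
  ghr <- if (inherits(hr, "raster_layer")) hr$grid else hr
  gc <- if (inherits(coarse, "raster_layer")) coarse$grid else coarse
  f <- gc$cellsize / ghr$cellsize
  if (abs(f - round(f)) > 1e-6) {
    stop("high-resolution grid does not nest integrally in the target grid")
  }
  f <- as.integer(round(f))
  if (ghr$nrow != gc$nrow * f || ghr$ncol != gc$ncol * f ||
      abs(ghr$xll - gc$xll) > 1e-9 || abs(ghr$yll - gc$yll) > 1e-9) {
    stop("high-resolution and target grids have incompatible extents")
  }
  f
}

# per-high-res-pixel linear index of the enclosing coarse pixel
coarse_index_map <- function(hr_grid, coarse_grid, f) {
  row_hr <- rep(seq_len(hr_grid$nrow), times = hr_grid$ncol)
  col_hr <- rep(seq_len(hr_grid$ncol), each = hr_grid$nrow)
  row_c <- (row_hr - 1L) %/% f + 1L
  col_c <- (col_hr - 1L) %/% f + 1L
  (col_c - 1L) * coarse_grid$nrow + row_c
}

#' Impervious area proportion (IAP)
#'
#' For each coarse pixel, the fraction of valid high-resolution land-cover
#' sub-pixels classified as impervious (category 1). Coarse pixels with no
#' valid sub-pixel become nodata.
#'
#' @param lulc_highres High-resolution `lulc` [raster_layer()].
#' @param target_grid Coarse [grid_spec()] in which the high-resolution
#'   grid nests integrally.
#' @return An `iap` [raster_layer()] on `target_grid`.
#' @export
compute_iap <- function(lulc_highres, target_grid) {
  stopifnot(inherits(lulc_highres, "raster_layer"),
            lulc_highres$kind == "lulc")
  f <- nesting_factor(lulc_highres, target_grid)
  idx <- coarse_index_map(lulc_highres$grid, target_grid, f)
  v <- as.vector(lulc_highres$values)
  nc <- target_grid$nrow * target_grid$ncol
  valid <- tabulate(idx[!is.na(v)], nbins = nc)
  imp <- tabulate(idx[!is.na(v) & v == 1], nbins = nc)
  out <- imp / valid
  out[valid == 0] <- NA_real_
  raster_layer(matrix(out, target_grid$nrow, target_grid$ncol),
               target_grid, kind = "iap")
}

#' Downscale categorical land cover to a coarse grid
#'
#' Each coarse pixel takes the modal category among its valid
#' high-resolution sub-pixels; ties are broken toward the lowest category
#' index. Coarse pixels with no valid sub-pixel become nodata.
#'
#' @inheritParams compute_iap
#' @return A coarse `lulc` [raster_layer()].
#' @export
downscale_lulc <- function(lulc_highres, target_grid) {
  stopifnot(inherits(lulc_highres, "raster_layer"),
            lulc_highres$kind == "lulc")
  f <- nesting_factor(lulc_highres, target_grid)
  idx <- coarse_index_map(lulc_highres$grid, target_grid, f)
  v <- as.vector(lulc_highres$values)
  nc <- target_grid$nrow * target_grid$ncol
  counts <- matrix(0L, nc, 7)
  for (cat in 1:7) {
    counts[, cat] <- tabulate(idx[!is.na(v) & v == cat], nbins = nc)
  }
  mode_cat <- max.col(counts, ties.method = "first")  # first = lowest index
  mode_cat[rowSums(counts) == 0] <- NA_integer_
  raster_layer(matrix(as.numeric(mode_cat), target_grid$nrow,
                      target_grid$ncol),
               target_grid, kind = "lulc")
}

#' Proximity to impervious area (PIA)
#'
#' For each pixel, the planar Euclidean distance in degrees from its centre
#' to the nearest impervious pixel centre is computed; within the search
#' radius PIA = `exp(-d / sigma_u)` (so impervious pixels themselves score
#' 1), beyond it PIA = 0. Pixels with missing values in the mask are
#' assigned 0. A mask with no impervious pixel yields an all-zero layer
#' with a warning.
#'
#' @param impervious_mask A `binary` [raster_layer()] (1 = impervious).
#' @param params A [pia_params()].
#' @return A `pia` [raster_layer()] on the mask's grid.
#' @export
compute_pia <- function(impervious_mask, params = pia_params()) {
  stopifnot(inherits(impervious_mask, "raster_layer"),
            inherits(params, "pia_params"))
  m <- impervious_mask$values
  if (!all(m[!is.na(m)] %in% c(0, 1))) {
    stop("impervious mask must be binary")
  }
  g <- impervious_mask$grid
  cc <- cell_centers(g)
  lon <- rep(cc$lon, each = g$nrow)
  lat <- rep(cc$lat, times = g$ncol)
  imp <- which(!is.na(as.vector(m)) & as.vector(m) == 1)
  out <- numeric(g$nrow * g$ncol)
  if (length(imp) == 0) {
    warning("impervious mask has no impervious pixels; PIA is all zero")
  } else {
    ilon <- lon[imp]; ilat <- lat[imp]
    # chunked vectorized nearest-neighbour search
    npix <- length(lon)
    chunk <- max(1L, as.integer(2e6 / length(imp)))
    for (s in seq(1L, npix, by = chunk)) {
      e <- min(npix, s + chunk - 1L)
      d2 <- outer(lon[s:e], ilon, "-")^2 + outer(lat[s:e], ilat, "-")^2
      dmin <- sqrt(.rowMins(d2))
      pia <- exp(-dmin / params$sigma_u)
      pia[dmin > params$search_radius] <- 0
      out[s:e] <- pia
    }
  }
  out[is.na(as.vector(m))] <- 0
  raster_layer(matrix(out, g$nrow, g$ncol), g, kind = "pia")
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Estimate the PIA decay scale from survey locations
#'
#' The population standard deviation (divisor N) of the nearest-impervious
#' planar distances, in degrees, over all cluster locations, without the
#' 1-degree truncation.
#'
#' @param clusters Cluster data frame (>= 2 rows).
#' @param impervious_mask A binary impervious [raster_layer()].
#' @return Estimated `sigma_u` in degrees.
#' @export
estimate_sigma_u <- function(clusters, impervious_mask) {
  if (nrow(clusters) < 2) stop("need at least 2 clusters")
  m <- impervious_mask$values
  g <- impervious_mask$grid
  imp <- which(!is.na(as.vector(m)) & as.vector(m) == 1)
  if (length(imp) == 0) stop("impervious mask has no impervious pixels")
  cc <- cell_centers(g)
  lon <- rep(cc$lon, each = g$nrow)[imp]
  lat <- rep(cc$lat, times = g$ncol)[imp]
  d <- vapply(seq_len(nrow(clusters)), function(i) {
    sqrt(min((clusters$lon[i] - lon)^2 + (clusters$lat[i] - lat)^2))
  }, numeric(1))
  sqrt(mean((d - mean(d))^2))
}

#' Assemble an aligned covariate stack
#'
#' @param grid The shared [grid_spec()].
#' @param layers Named list (by year) of lists with `ntl`, `lulc`, `iap`,
#'   `pia` rasters, all on `grid`.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, layers) {
  for (yr in names(layers)) {
    lay <- layers[[yr]]
    stopifnot(all(c("ntl", "lulc", "iap", "pia") %in% names(lay)))
    for (nm in c("ntl", "lulc", "iap", "pia")) {
      if (!same_grid(lay[[nm]], grid)) {
        stop("layer ", nm, " for year ", yr, " is not on the stack grid")
      }
    }
  }
  structure(list(grid = grid, years = as.integer(names(layers)),
                 layers = layers),
            class = "covariate_stack")
}

#' Build the model covariate stack from a synthetic landscape
#'
#' Runs the standard covariate engineering per year: IAP and modal
#' land-cover downscaling from the high-resolution layer, and PIA from the
#' coarse impervious-bearing mask (any coarse pixel with IAP > 0 counts as
#' impervious; set `pia_source = "highres"` to search the high-resolution
#' mask instead).
#'
#' @param landscape Output of [generate_landscape()].
#' @param params A [pia_params()].
#' @param pia_source `"coarse"` (default) or `"highres"`.
#' @return A [covariate_stack()].
#' @export
build_covariates <- function(landscape, params = pia_params(),
                             pia_source = c("coarse", "highres")) {
  pia_source <- match.arg(pia_source)
  g <- landscape$grid
  layers <- list()
  for (t in landscape$years) {
    yr <- as.character(t)
    iap <- compute_iap(landscape$lulc[[yr]], g)
    lulc5 <- downscale_lulc(landscape$lulc[[yr]], g)
    if (pia_source == "coarse") {
      mask_vals <- ifelse(is.na(iap$values), NA,
                          as.numeric(iap$values > 0))
      mask <- raster_layer(mask_vals, g, kind = "binary")
    } else {
      hr <- landscape$lulc[[yr]]
      mask <- raster_layer(
        ifelse(is.na(hr$values), NA, as.numeric(hr$values == 1)),
        hr$grid, kind = "binary")
    }
    pia <- suppressWarnings(compute_pia(mask, params))
    if (pia_source == "highres") {
      # sample the high-resolution PIA surface at coarse pixel centres
      f <- nesting_factor(pia, g)
      rows <- (seq_len(g$nrow) - 1L) * f + (f + 1L) %/% 2L
      cols <- (seq_len(g$ncol) - 1L) * f + (f + 1L) %/% 2L
      pia <- raster_layer(pia$values[rows, cols], g, kind = "pia")
    }
    layers[[yr]] <- list(ntl = landscape$ntl[[yr]], lulc = lulc5,
                         iap = iap, pia = pia)
  }
  covariate_stack(g, layers)
}

obs_table <- function(df) {
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Extract buffer-averaged covariates at cluster locations
#'
#' Continuous covariates (`ntl`, `iap`, `pia`) are averaged over all valid
#' pixels whose centres lie within `buffer_km` (great-circle) of the
#' cluster point; the land-cover category is the modal category within the
#' buffer (ties to the lowest index). Clusters whose buffer contains no
#' valid pixel are dropped; their ids are attached as the `"dropped"`
#' attribute and reported in a message.
#'
#' @param stack A [covariate_stack()] covering every cluster year.
#' @param clusters Cluster data frame.
#' @param buffer_km Buffer radius in km (default 5); must be at least half
#'   the pixel diagonal so every buffer can contain a pixel centre.
#' @return An observation table: cluster fields, response `(k, n)` and the
#'   covariate columns `ntl`, `lulc`, `iap`, `pia`.
#' @export
extract_buffer_covariates <- function(stack, clusters, buffer_km = 5) {
  stopifnot(inherits(stack, "covariate_stack"))
  g <- stack$grid
  min_km <- 0.5 * g$cellsize * sqrt(2) * KM_PER_DEG
  if (buffer_km < min_km) {
    stop(sprintf(
      "buffer_km = %g is smaller than half the pixel diagonal; use at least %.2f km",
      buffer_km, min_km))
  }
  if (!all(clusters$year %in% stack$years)) {
    stop("covariate stack does not cover all cluster years")
  }
  cc <- cell_centers(g)
  n <- nrow(clusters)
  ntl <- iap <- pia <- rep(NA_real_, n)
  lulc <- rep(NA_integer_, n)
  half_w <- ceiling(buffer_km / KM_PER_DEG / g$cellsize) + 1L
  for (i in seq_len(n)) {
    lay <- stack$layers[[as.character(clusters$year[i])]]
    # candidate window around the cluster, then exact great-circle filter
    ctr <- point_to_cell(g, clusters$lon[i], clusters$lat[i])
    r0 <- if (is.na(ctr$row)) round((grid_ytop(g) - clusters$lat[i]) /
                                      g$cellsize) else ctr$row
    c0 <- if (is.na(ctr$col)) round((clusters$lon[i] - g$xll) /
                                      g$cellsize) else ctr$col
    rows <- max(1, r0 - half_w):min(g$nrow, r0 + half_w)
    cols <- max(1, c0 - half_w):min(g$ncol, c0 + half_w)
    if (length(rows) == 0 || length(cols) == 0) next
    plon <- rep(cc$lon[cols], each = length(rows))
    plat <- rep(cc$lat[rows], times = length(cols))
    d <- geosphere::distHaversine(c(clusters$lon[i], clusters$lat[i]),
                                  cbind(plon, plat)) / 1000
    sel <- d <= buffer_km
    if (!any(sel)) next
    sub <- cbind(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))[sel, , drop = FALSE]
    vntl <- lay$ntl$values[sub]; vlulc <- lay$lulc$values[sub]
    viap <- lay$iap$values[sub]; vpia <- lay$pia$values[sub]
    if (any(!is.na(vntl))) ntl[i] <- mean(vntl, na.rm = TRUE)
    if (any(!is.na(viap))) iap[i] <- mean(viap, na.rm = TRUE)
    if (any(!is.na(vpia))) pia[i] <- mean(vpia, na.rm = TRUE)
    if (any(!is.na(vlulc))) {
      cnt <- tabulate(vlulc[!is.na(vlulc)], nbins = 7)
      lulc[i] <- which.max(cnt)  # which.max takes the lowest index on ties
    }
  }
  keep <- !is.na(ntl) & !is.na(lulc) & !is.na(iap) & !is.na(pia)
  dropped <- clusters$cluster_id[!keep]
  if (length(dropped)) {
    message(length(dropped),
            " cluster(s) dropped: no valid covariate pixel in buffer")
  }
  out <- data.frame(
    cluster_id = clusters$cluster_id, lon = clusters$lon,
    lat = clusters$lat, year = clusters$year,
    country = clusters$country, urban = clusters$urban,
    k = clusters$n_electrified, n = clusters$n_households,
    ntl = ntl, lulc = lulc, iap = iap, pia = pia,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  obs_table(out)
}

#' Extract at-pixel covariates at cluster locations
#'
#' Covariate values of the single pixel containing each cluster point (the
#' exact design the truth surface was generated from); clusters on nodata
#' pixels or outside the grid are dropped.
#'
#' @inheritParams extract_buffer_covariates
#' @return An observation table as in [extract_buffer_covariates()].
#' @export
extract_pixel_covariates <- function(stack, clusters) {
  stopifnot(inherits(stack, "covariate_stack"))
  g <- stack$grid
  cells <- point_to_cell(g, clusters$lon, clusters$lat)
  n <- nrow(clusters)
  ntl <- iap <- pia <- rep(NA_real_, n)
  lulc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(cells$row[i])) next
    lay <- stack$layers[[as.character(clusters$year[i])]]
    if (is.null(lay)) stop("covariate stack does not cover year ",
                           clusters$year[i])
    rc <- cbind(cells$row[i], cells$col[i])
    ntl[i] <- lay$ntl$values[rc]
    lulc[i] <- lay$lulc$values[rc]
    iap[i] <- lay$iap$values[rc]
    pia[i] <- lay$pia$values[rc]
  }
  keep <- !is.na(ntl) & !is.na(lulc) & !is.na(iap) & !is.na(pia)
  dropped <- clusters$cluster_id[!keep]
  if (length(dropped)) {
    message(length(dropped),
            " cluster(s) dropped: nodata or outside grid")
  }
  out <- data.frame(
    cluster_id = clusters$cluster_id, lon = clusters$lon,
    lat = clusters$lat, year = clusters$year,
    country = clusters$country, urban = clusters$urban,
    k = clusters$n_electrified, n = clusters$n_households,
    ntl = ntl, lulc = lulc, iap = iap, pia = pia,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  obs_table(out)
}
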