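# build a high-resolution lulc layer from an explicit matrix
hr_lulc <- function(m, coarse, f) {
  hr <- grid_spec(coarse$nrow * f, coarse$ncol * f, coarse$xll,
                  coarse$yll, coarse$cellsize / f)
  raster_layer(m, hr, kind = "lulc")
}

test_that("IAP counts impervious sub-pixels per coarse pixel", {
  coarse <- grid_spec(1, 1, 0, 0, 0.5)
  m <- matrix(2, 10, 10)
  m[1:5, 1:5] <- 1  # 25 impervious of 100
  expect_equal(compute_iap(hr_lulc(m, coarse, 10), coarse)$values[1, 1],
               0.25)
  expect_equal(compute_iap(hr_lulc(matrix(1, 10, 10), coarse, 10),
                           coarse)$values[1, 1], 1)
  expect_equal(compute_iap(hr_lulc(matrix(3, 10, 10), coarse, 10),
                           coarse)$values[1, 1], 0)
  # all sub-pixels missing -> nodata; partial missing -> valid-only share
  m2 <- matrix(NA_real_, 10, 10); m2[1, 1] <- 1; m2[1, 2] <- 4
  expect_equal(compute_iap(hr_lulc(m2, coarse, 10), coarse)$values[1, 1],
               0.5)
  expect_true(is.na(compute_iap(hr_lulc(matrix(NA_real_, 10, 10),
                                        coarse, 10),
                                coarse)$values[1, 1]))
})

test_that("LULC downscaling takes the modal category, ties to lowest", {
  coarse <- grid_spec(1, 1, 0, 0, 0.5)
  expect_equal(downscale_lulc(hr_lulc(matrix(3, 10, 10), coarse, 10),
                              coarse)$values[1, 1], 3)
  m_tie <- matrix(c(rep(2, 50), rep(4, 50)), 10, 10)
  expect_equal(downscale_lulc(hr_lulc(m_tie, coarse, 10),
                              coarse)$values[1, 1], 2)
  m_mix <- matrix(c(rep(1, 30), rep(2, 60), rep(7, 10)), 10, 10)
  expect_equal(downscale_lulc(hr_lulc(m_mix, coarse, 10),
                              coarse)$values[1, 1], 2)
})

test_that("aggregation rejects non-nesting grids", {
  coarse <- grid_spec(2, 2, 0, 0, 0.5)
  hr <- grid_spec(7, 7, 0, 0, 0.5 / 3.5)
  lay <- raster_layer(matrix(2, 7, 7), hr, kind = "lulc")
  expect_error(compute_iap(lay, coarse), "nest")
  hr2 <- grid_spec(6, 6, 0.1, 0, 0.5 / 3)
  lay2 <- raster_layer(matrix(2, 6, 6), hr2, kind = "lulc")
  expect_error(compute_iap(lay2, coarse), "incompatible")
})

test_that("PIA follows the exponential decay with the 1-degree cutoff", {
  g <- grid_spec(1, 40, 0, 0, 0.04)
  m <- matrix(0, 1, 40); m[1, 1] <- 1
  pia <- compute_pia(raster_layer(m, g, kind = "binary"),
                     pia_params(sigma_u = 0.28, search_radius = 1))
  expect_equal(pia$values[1, 1], 1)                      # exp(0)
  expect_equal(pia$values[1, 8], exp(-1), tolerance = 1e-12)  # d = 0.28
  # pixels farther than 1 degree from the only impervious pixel are zero
  expect_true(all(pia$values[1, 27:40] == 0))
  expect_gt(pia$values[1, 26], 0)
  # monotone non-increasing in distance
  expect_true(all(diff(pia$values[1, ]) <= 1e-15))
})

test_that("PIA treats missing pixels and empty masks as zero", {
  g <- grid_spec(3, 3, 0, 0, 0.04)
  m <- matrix(0, 3, 3); m[1, 1] <- 1; m[3, 3] <- NA
  pia <- compute_pia(raster_layer(m, g, kind = "binary"))
  expect_equal(pia$values[3, 3], 0)
  expect_warning(
    empty <- compute_pia(raster_layer(matrix(0, 3, 3), g,
                                      kind = "binary")),
    "no impervious")
  expect_true(all(empty$values == 0))
})

test_that("PIA equals the brute-force nearest-distance oracle", {
  g <- grid_spec(30, 30, 0, 0, 0.04)
  set.seed(42)
  m <- matrix(0, 30, 30)
  m[sample(900, 12)] <- 1
  params <- pia_params(sigma_u = 0.28, search_radius = 1)
  fast <- compute_pia(raster_layer(m, g, kind = "binary"), params)
  cc <- cell_centers(g)
  imp <- which(m == 1, arr.ind = TRUE)
  oracle <- matrix(NA_real_, 30, 30)
  for (r in 1:30) for (c2 in 1:30) {
    d <- sqrt(min((cc$lon[c2] - cc$lon[imp[, 2]])^2 +
                    (cc$lat[r] - cc$lat[imp[, 1]])^2))
    oracle[r, c2] <- if (d > 1) 0 else exp(-d / 0.28)
  }
  expect_equal(fast$values, oracle, tolerance = 1e-12)
})

test_that("sigma_u is the population sd of nearest-impervious distances", {
  g <- grid_spec(1, 1, 0, 0, 0.05)
  mask <- raster_layer(matrix(1, 1, 1), g, kind = "binary")
  ctr_lon <- 0.025; ctr_lat <- 0.025
  cl <- data.frame(cluster_id = c("a", "b"),
                   lon = c(ctr_lon + 0.1, ctr_lon + 0.3),
                   lat = c(ctr_lat, ctr_lat))
  expect_equal(estimate_sigma_u(cl, mask), 0.1, tolerance = 1e-12)
  on_mask <- data.frame(cluster_id = c("a", "b"),
                        lon = c(ctr_lon, ctr_lon),
                        lat = c(ctr_lat, ctr_lat))
  expect_equal(estimate_sigma_u(on_mask, mask), 0)
  expect_error(estimate_sigma_u(cl[1, ], mask), "at least 2")
  empty <- raster_layer(matrix(0, 1, 1), g, kind = "binary")
  expect_error(estimate_sigma_u(cl, empty), "no impervious")
})

test_that("buffer covariates average valid pixels in the buffer", {
  g <- grid_spec(10, 10, 30, 0, 0.045)
  mk <- function(vals, kind) raster_layer(vals, g, kind = kind)
  uniform <- list("2000" = list(
    ntl = mk(matrix(10, 10, 10), "ntl"),
    lulc = mk(matrix(3, 10, 10), "lulc"),
    iap = mk(matrix(0.2, 10, 10), "iap"),
    pia = mk(matrix(0.7, 10, 10), "pia")))
  stack <- covariate_stack(g, uniform)
  cl <- data.frame(
    cluster_id = "c1", lon = 30.2, lat = 0.22, year = 2000L,
    country = "R1", urban = FALSE, n_households = 24L,
    n_electrified = 10L, displaced = FALSE)
  obs <- extract_buffer_covariates(stack, cl, buffer_km = 5)
  expect_equal(obs$ntl, 10)
  expect_equal(obs$iap, 0.2)
  expect_equal(obs$lulc, 3)

  # split field: left half iap 0.2, right half 0.6, cluster on the divide
  iap_split <- matrix(0.2, 10, 10); iap_split[, 6:10] <- 0.6
  split_layers <- uniform
  split_layers[["2000"]]$iap <- mk(iap_split, "iap")
  stack2 <- covariate_stack(g, split_layers)
  cl2 <- cl; cl2$lon <- 30 + 5 * 0.045; cl2$lat <- 0.225
  obs2 <- extract_buffer_covariates(stack2, cl2, buffer_km = 5)
  expect_equal(obs2$iap, 0.4, tolerance = 1e-9)
})

test_that("clusters without valid buffer pixels are dropped and logged", {
  g <- grid_spec(10, 10, 30, 0, 0.045)
  na_lay <- list("2000" = list(
    ntl = raster_layer(matrix(NA_real_, 10, 10), g, "ntl"),
    lulc = raster_layer(matrix(NA_real_, 10, 10), g, "lulc"),
    iap = raster_layer(matrix(NA_real_, 10, 10), g, "iap"),
    pia = raster_layer(matrix(NA_real_, 10, 10), g, "pia")))
  stack <- covariate_stack(g, na_lay)
  cl <- data.frame(
    cluster_id = "c1", lon = 30.2, lat = 0.2, year = 2000L,
    country = "R1", urban = FALSE, n_households = 24L,
    n_electrified = 10L, displaced = FALSE)
  expect_message(obs <- extract_buffer_covariates(stack, cl, 5),
                 "dropped")
  expect_identical(nrow(obs), 0L)
  expect_identical(attr(obs, "dropped"), "c1")
})

test_that("too-small buffers and uncovered years are rejected", {
  w <- tiny_world(dim = 8, n_clusters = 20, seed = 14)
  expect_error(extract_buffer_covariates(w$stack, w$clusters, 0.5),
               "at least")
  future <- w$clusters
  future$year <- 2050L
  expect_error(extract_buffer_covariates(w$stack, future, 5),
               "cover")
})
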