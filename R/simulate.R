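#' Simulation configuration for synthetic study landscapes
#'
#' Bundles every knob of the synthetic-data generator: the working grid, the
#' urban-centre layout, the ground-truth fixed effects and Matern field
#' hyperparameters, and the cluster-sampling model (mean cluster size 24
#' households, sizes truncated to `[1, household_size_max]`).
#'
#' The `beta_true` vector is named on the model's design scale: intercept,
#' `ntl` (luminosity scaled by 1/63), land-cover dummies `lulc1`,
#' `lulc3`..`lulc7` (low biomass, category 2, is the reference), `iap`,
#' `pia`, and `year` (centred mid-window, scaled to \[-1, 1\]).
#'
#' @param grid Working [grid_spec()] (default 30 x 30 pixels of 0.045 deg).
#' @param n_urban_centers Number of urban centres seeding lights/impervious
#'   cover.
#' @param years Study years.
#' @param beta_true Named ground-truth fixed-effect vector.
#' @param matern_range_true Matern (nu = 1) range of the latent field,
#'   degrees.
#' @param matern_sd_true Marginal standard deviation of the latent field on
#'   the logit scale.
#' @param n_clusters Number of survey clusters to draw.
#' @param household_size_mean Mean households per cluster.
#' @param household_size_max Upper truncation for cluster sizes.
#' @param urban_fraction Fraction of clusters flagged urban.
#' @param subgrid_factor High-resolution land-cover grid refinement factor.
#' @param ntl_growth Yearly relative growth of light intensity.
#' @param pop_total Total population on the grid in the first quinquennium.
#' @param pop_growth Population growth factor per quinquennium.
#' @param seed Integer RNG seed; derived streams use small fixed offsets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid = grid_spec(30, 30, 30, -1, 0.045),
                       n_urban_centers = 5,
                       years = 2000:2013,
                       beta_true = c("(Intercept)" = -1.0, ntl = 2.0,
                                     lulc1 = 0.5, lulc3 = -0.3,
                                     lulc4 = -0.2, lulc5 = -0.4,
                                     lulc6 = -0.3, lulc7 = -0.5,
                                     iap = 1.5, pia = 1.5, year = 0.8),
                       matern_range_true = 0.3,
                       matern_sd_true = 1.0,
                       n_clusters = 800,
                       household_size_mean = 24,
                       household_size_max = 120,
                       urban_fraction = 0.35,
                       subgrid_factor = 3,
                       ntl_growth = 0.02,
                       pop_total = 1e6,
                       pop_growth = 1.12,
                       seed = 1) {
  stopifnot(inherits(grid, "grid_spec"),
            household_size_mean >= 1,
            household_size_max >= 1,
            urban_fraction >= 0, urban_fraction <= 1,
            matern_range_true > 0, matern_sd_true >= 0,
            subgrid_factor >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# smooth kernel intensity from urban centres, evaluated at pixel centres
kernel_intensity <- function(grid, centers) {
  cc <- cell_centers(grid)
  lon <- matrix(cc$lon, grid$nrow, grid$ncol, byrow = TRUE)
  lat <- matrix(cc$lat, grid$nrow, grid$ncol)
  u <- matrix(0, grid$nrow, grid$ncol)
  if (is.null(centers) || nrow(centers) == 0) return(u)
  for (i in seq_len(nrow(centers))) {
    d2 <- (lon - centers$lon[i])^2 + (lat - centers$lat[i])^2
    u <- u + centers$w[i] * exp(-d2 / (2 * centers$s[i]^2))
  }
  u
}

#' Generate a synthetic nighttime-lights and land-cover landscape
#'
#' Draws `n_urban_centers` urban centres, builds annual 6-bit
#' nighttime-light rasters (integer 0-63, brightest at the centres, mild
#' year-on-year growth) on the working grid, and annual high-resolution
#' 7-category land-cover rasters in which impervious pixels (category 1)
#' cluster around the centres and slowly expand, while categories 2-7 fill
#' the remaining space from a smooth random field. Deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return List with `grid`, `hr_grid`, `years`, `centers`, `ntl` (named
#'   list of coarse `ntl` rasters per year) and `lulc` (named list of
#'   high-resolution `lulc` rasters per year).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  f <- as.integer(config$subgrid_factor)
  if (config$n_urban_centers > g$nrow * g$ncol) {
    stop("n_urban_centers exceeds the number of grid pixels")
  }
  hr <- grid_spec(g$nrow * f, g$ncol * f, g$xll, g$yll, g$cellsize / f)
  t0 <- min(config$years)
  with_seed(config$seed, {
    nc <- config$n_urban_centers
    centers <- if (nc > 0) {
      data.frame(
        lon = runif(nc, g$xll + 0.1 * (grid_xmax(g) - g$xll),
                    grid_xmax(g) - 0.1 * (grid_xmax(g) - g$xll)),
        lat = runif(nc, g$yll + 0.1 * (grid_ytop(g) - g$yll),
                    grid_ytop(g) - 0.1 * (grid_ytop(g) - g$yll)),
        s = runif(nc, 0.05, 0.12),
        w = runif(nc, 0.6, 1.0))
    } else data.frame(lon = numeric(0), lat = numeric(0),
                      s = numeric(0), w = numeric(0))
    u <- kernel_intensity(g, centers)
    u_hr <- kernel_intensity(hr, centers)
    eps <- matrix(runif(hr$nrow * hr$ncol), hr$nrow, hr$ncol)
    # background land-cover texture: a few broad random blobs
    nb <- 8
    blobs <- data.frame(
      lon = runif(nb, g$xll, grid_xmax(g)),
      lat = runif(nb, g$yll, grid_ytop(g)),
      s = runif(nb, 0.15, 0.5),
      w = runif(nb, -1, 1))
    v <- kernel_intensity(hr, blobs) +
      matrix(rnorm(hr$nrow * hr$ncol, sd = 0.05), hr$nrow, hr$ncol)
    # categories 2..7 by area shares of the background field
    shares <- c(0.40, 0.18, 0.15, 0.10, 0.09, 0.08)
    qs <- stats::quantile(v, probs = cumsum(shares)[-length(shares)])
    base_cat <- matrix(2, hr$nrow, hr$ncol)
    for (j in seq_along(qs)) base_cat[v > qs[j]] <- j + 2
    p_imp <- pmax(pmin(1.8 * u_hr - 0.35, 1), 0)
    ntl <- list(); lulc <- list()
    for (t in config$years) {
      grow <- (1 + config$ntl_growth)^(t - t0)
      vals <- round(pmin(63 * pmin(u, 1) * grow, 63))
      ntl[[as.character(t)]] <- raster_layer(vals, g, kind = "ntl")
      imp_t <- eps < pmin(1, p_imp * (1 + 0.015 * (t - t0)))
      cat_t <- base_cat
      cat_t[imp_t] <- 1
      lulc[[as.character(t)]] <- raster_layer(cat_t, hr, kind = "lulc")
    }
    list(grid = g, hr_grid = hr, years = config$years, centers = centers,
         ntl = ntl, lulc = lulc)
  })
}

#' Simulate a Matern (nu = 1) Gaussian field on a grid
#'
#' Exact simulation by Cholesky factorisation of the dense Matern covariance
#' between pixel centres (planar distances in degrees), intended for
#' desk-scale grids. The range parameter follows the common convention
#' \eqn{\kappa = \sqrt{8\nu}/\rho}, i.e. correlation approximately 0.13 at
#' distance `rho`.
#'
#' @param grid A [grid_spec()].
#' @param rho Range in degrees.
#' @param sigma Marginal standard deviation (0 gives a zero field).
#' @param seed Integer seed.
#' @return Matrix of field values on the grid.
#' @export
simulate_matern_field <- function(grid, rho, sigma, seed) {
  n <- grid$nrow * grid$ncol
  if (sigma == 0) return(matrix(0, grid$nrow, grid$ncol))
  stopifnot(rho > 0, sigma > 0)
  cc <- cell_centers(grid)
  lon <- rep(cc$lon, each = grid$nrow)
  lat <- rep(cc$lat, times = grid$ncol)
  d <- as.matrix(stats::dist(cbind(lon, lat)))
  kappa <- sqrt(8) / rho
  C <- sigma^2 * (kappa * d) * besselK(kappa * d, 1)
  C[d == 0] <- sigma^2
  C <- C + diag(1e-8, n)
  L <- chol(C)
  z <- with_seed(seed, rnorm(n))
  matrix(drop(crossprod(L, z)), grid$nrow, grid$ncol)
}

# design-scale year covariate: centred mid-window, scaled to [-1, 1]
scale_year <- function(year, year_range) {
  if (diff(year_range) == 0) return(rep(0, length(year)))
  2 * (year - mean(year_range)) / diff(year_range)
}

# full-dummy truth design at grid pixels for one year's covariate layers
truth_design <- function(layers, year, year_range) {
  ntl <- as.vector(layers$ntl$values) / 63
  lulc <- as.vector(layers$lulc$values)
  iap <- as.vector(layers$iap$values)
  pia <- as.vector(layers$pia$values)
  X <- cbind(`(Intercept)` = 1, ntl = ntl)
  for (cat in c(1, 3, 4, 5, 6, 7)) {
    X <- cbind(X, as.numeric(lulc == cat))
    colnames(X)[ncol(X)] <- paste0("lulc", cat)
  }
  cbind(X, iap = iap, pia = pia,
        year = scale_year(rep(year, length(ntl)), year_range))
}

#' Generate the ground-truth probability surface
#'
#' Builds, for each study year, the probability-of-access surface
#' \eqn{p(x, t) = \mathrm{logit}^{-1}(x(x,t)'\beta + S(x))} from the
#' covariate stack, the configured true coefficients and one shared draw of
#' a Matern (nu = 1) spatial field with range `matern_range_true` and
#' marginal sd `matern_sd_true`. With `matern_sd_true = 0` the surface is a
#' deterministic function of the covariates.
#'
#' @param config A [sim_config()].
#' @param stack A [covariate_stack()] aligned to `config$grid`.
#' @return List with `prob` (named list of probability rasters per year),
#'   `field` (matrix of latent values) and `beta_true`.
#' @export
generate_truth_surface <- function(config, stack) {
  stopifnot(inherits(config, "sim_config"),
            inherits(stack, "covariate_stack"))
  if (!same_grid(config$grid, stack$grid)) {
    stop("covariate stack grid is not aligned with the simulation grid")
  }
  g <- config$grid
  yr_range <- range(config$years)
  S <- simulate_matern_field(g, config$matern_range_true,
                             config$matern_sd_true, config$seed + 1L)
  beta <- config$beta_true
  prob <- list()
  for (t in config$years) {
    yr <- as.character(t)
    if (is.null(stack$layers[[yr]])) {
      stop("covariate stack has no layers for year ", yr)
    }
    X <- truth_design(stack$layers[[yr]], t, yr_range)
    b <- beta[colnames(X)]
    b[is.na(b)] <- 0
    eta <- drop(X %*% b) + as.vector(S)
    p <- matrix(plogis(eta), g$nrow, g$ncol)
    prob[[yr]] <- raster_layer(p, g, kind = "probability")
  }
  list(prob = prob, field = S, beta_true = beta)
}

#' Sample survey clusters from a truth surface
#'
#' Draws cluster locations (urban clusters preferentially on
#' impervious-bearing pixels, rural clusters elsewhere), cluster sizes from
#' a shifted Poisson `1 + Poisson(mean - 1)` truncated to
#' `[1, household_size_max]`, and electrified counts
#' `k ~ Binomial(n, p)` at the cluster's pixel for its survey year.
#'
#' @param truth Output of [generate_truth_surface()].
#' @param stack The [covariate_stack()] (supplies the impervious mask used
#'   to place urban clusters).
#' @param config A [sim_config()].
#' @return A cluster data frame (see [read_clusters()]) with
#'   `displaced = FALSE`.
#' @export
sample_clusters <- function(truth, stack, config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- config$n_clusters
  if (nc == 0) stop("n_clusters must be positive")
  g <- config$grid
  years <- config$years
  with_seed(config$seed + 2L, {
    year_i <- years[sample.int(length(years), nc, replace = TRUE)]
    urban_i <- runif(nc) < config$urban_fraction
    lon <- numeric(nc); lat <- numeric(nc); p_i <- numeric(nc)
    for (t in unique(year_i)) {
      yr <- as.character(t)
      sel <- which(year_i == t)
      lay <- stack$layers[[yr]]
      imp <- !is.na(lay$iap$values) & lay$iap$values > 0
      for (j in sel) {
        pool <- if (urban_i[j] && any(imp)) which(imp) else
          if (!urban_i[j] && any(!imp)) which(!imp) else
            seq_len(g$nrow * g$ncol)
        px <- if (length(pool) == 1) pool else sample(pool, 1)
        row <- (px - 1) %% g$nrow + 1
        col <- (px - 1) %/% g$nrow + 1
        lon[j] <- g$xll + (col - 1 + runif(1)) * g$cellsize
        lat[j] <- grid_ytop(g) - (row - 1 + runif(1)) * g$cellsize
        p_i[j] <- truth$prob[[yr]]$values[row, col]
      }
    }
    n_i <- 1L + rpois(nc, config$household_size_mean - 1)
    while (any(bad <- n_i > config$household_size_max)) {
      n_i[bad] <- 1L + rpois(sum(bad), config$household_size_mean - 1)
    }
    k_i <- rbinom(nc, n_i, p_i)
    validate_clusters(data.frame(
      cluster_id = sprintf("cl%05d", seq_len(nc)),
      lon = lon, lat = lat, year = as.integer(year_i),
      country = ifelse(lon < (g$xll + grid_xmax(g)) / 2, "R1", "R2"),
      urban = urban_i, n_households = n_i, n_electrified = k_i,
      displaced = FALSE), range(years))
  })
}

#' DHS-style displacement rule
#'
#' Maximum jitter distances: urban points up to `urban_max_km` (2 km),
#' rural points up to `rural_max_km` (5 km) except a `rural_far_fraction`
#' (1%) moved up to `rural_far_max_km` (10 km).
#'
#' @param urban_max_km,rural_max_km,rural_far_max_km Maximum displacement
#'   distances in km.
#' @param rural_far_fraction Probability a rural point uses the far cap.
#' @return An object of class `displacement_rule`.
#' @export
displacement_rule <- function(urban_max_km = 2, rural_max_km = 5,
                              rural_far_max_km = 10,
                              rural_far_fraction = 0.01) {
  stopifnot(urban_max_km >= 0, rural_max_km >= 0,
            rural_max_km <= rural_far_max_km,
            rural_far_fraction >= 0, rural_far_fraction <= 1)
  structure(list(urban_max_km = urban_max_km, rural_max_km = rural_max_km,
                 rural_far_max_km = rural_far_max_km,
                 rural_far_fraction = rural_far_fraction),
            class = "displacement_rule")
}

#' Displace cluster coordinates DHS-style
#'
#' Each cluster is moved along a uniform random bearing by a uniform random
#' distance in `[0, max_km]`, where `max_km` follows the
#' [displacement_rule()]: the far-rural subset is chosen by independent
#' Bernoulli draws. Destinations are computed on the sphere (geodesic
#' destination point), so the great-circle displacement never exceeds the
#' cap. All non-coordinate fields are preserved; the input is not modified.
#'
#' @param clusters Cluster data frame with `displaced = FALSE` throughout.
#' @param rule A [displacement_rule()].
#' @param seed Integer seed.
#' @return A new cluster data frame with jittered coordinates and
#'   `displaced = TRUE`.
#' @export
displace_clusters <- function(clusters, rule = displacement_rule(),
                              seed = 1) {
  stopifnot(inherits(rule, "displacement_rule"))
  if (any(clusters$displaced)) {
    stop("clusters are already displaced; refusing to jitter twice")
  }
  n <- nrow(clusters)
  out <- clusters
  with_seed(seed, {
    bearing <- runif(n, 0, 360)
    far <- !clusters$urban & runif(n) < rule$rural_far_fraction
    max_km <- ifelse(clusters$urban, rule$urban_max_km,
                     ifelse(far, rule$rural_far_max_km, rule$rural_max_km))
    dist_m <- runif(n, 0, max_km) * 1000
    dest <- dest_point(clusters$lon, clusters$lat, bearing, dist_m)
    out$lon <- dest[, 1]
    out$lat <- dest[, 2]
  })
  out$displaced <- TRUE
  out
}

#' Generate quinquennial population rasters
#'
#' Population density is concentrated around the landscape's urban centres
#' with a lognormal texture, scaled to `pop_total` in the first listed year
#' and grown by `pop_growth` per quinquennium (uniform across pixels).
#'
#' @param config A [sim_config()].
#' @param quinquennial_years Sorted snapshot years, default
#'   `c(2000, 2005, 2010, 2015)`.
#' @return Named list of `population` rasters, one per listed year.
#' @export
generate_population <- function(config,
                                quinquennial_years = c(2000, 2005,
                                                       2010, 2015)) {
  stopifnot(inherits(config, "sim_config"),
            !is.unsorted(quinquennial_years))
  g <- config$grid
  with_seed(config$seed, {
    nc <- config$n_urban_centers
    centers <- if (nc > 0) {
      data.frame(
        lon = runif(nc, g$xll + 0.1 * (grid_xmax(g) - g$xll),
                    grid_xmax(g) - 0.1 * (grid_xmax(g) - g$xll)),
        lat = runif(nc, g$yll + 0.1 * (grid_ytop(g) - g$yll),
                    grid_ytop(g) - 0.1 * (grid_ytop(g) - g$yll)),
        s = runif(nc, 0.05, 0.12),
        w = runif(nc, 0.6, 1.0))
    } else data.frame(lon = numeric(0), lat = numeric(0),
                      s = numeric(0), w = numeric(0))
    u <- kernel_intensity(g, centers)
    noise <- with_seed(config$seed + 3L,
                       matrix(exp(rnorm(g$nrow * g$ncol, sd = 0.3)),
                              g$nrow, g$ncol))
    dens <- (u + 0.05) * noise
    base <- config$pop_total * dens / sum(dens)
    out <- list()
    for (q in seq_along(quinquennial_years)) {
      vals <- base * config$pop_growth^(q - 1)
      out[[as.character(quinquennial_years[q])]] <-
        raster_layer(vals, g, kind = "population")
    }
    out
  })
}
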