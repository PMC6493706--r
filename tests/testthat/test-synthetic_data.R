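test_that("generated nighttime lights honour the 6-bit range", {
  w <- tiny_world(dim = 12, seed = 4)
  for (lay in w$land$ntl) {
    v <- lay$values[!is.na(lay$values)]
    expect_true(all(v >= 0 & v <= 63))
    expect_true(all(v == round(v)))
  }
})

test_that("a landscape with no urban centres is dark and unbuilt", {
  cfg <- sim_config(grid = grid_spec(10, 10, 30, -1, 0.045),
                    years = 2000, n_urban_centers = 0, seed = 2)
  land <- generate_landscape(cfg)
  expect_true(all(land$ntl[["2000"]]$values == 0))
  expect_false(any(land$lulc[["2000"]]$values == 1))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  a <- generate_landscape(sim_config(grid = grid_spec(10, 10, 30, -1,
                                                      0.045),
                                     years = c(2000, 2001), seed = 11))
  b <- generate_landscape(sim_config(grid = grid_spec(10, 10, 30, -1,
                                                      0.045),
                                     years = c(2000, 2001), seed = 11))
  expect_identical(a$ntl[["2001"]]$values, b$ntl[["2001"]]$values)
  expect_identical(a$lulc[["2000"]]$values, b$lulc[["2000"]]$values)
  c2 <- generate_landscape(sim_config(grid = grid_spec(10, 10, 30, -1,
                                                       0.045),
                                      years = c(2000, 2001), seed = 12))
  expect_false(identical(a$ntl[["2000"]]$values,
                         c2$ntl[["2000"]]$values))
})

test_that("truth surface reduces to 0.5 with zero effects and field", {
  cfg <- sim_config(grid = grid_spec(8, 8, 30, -1, 0.045), years = 2000,
                    beta_true = c("(Intercept)" = 0), matern_sd_true = 0,
                    seed = 3)
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  truth <- generate_truth_surface(cfg, stack)
  expect_true(all(truth$prob[["2000"]]$values == 0.5))
  # and is a deterministic function of covariates when sigma_s = 0
  truth2 <- generate_truth_surface(cfg, stack)
  expect_identical(truth$prob[["2000"]]$values,
                   truth2$prob[["2000"]]$values)
})

test_that("truth probabilities stay strictly inside (0, 1)", {
  w <- tiny_world(dim = 12, seed = 5)
  for (lay in w$truth$prob) {
    expect_true(min(lay$values) > 0)
    expect_true(max(lay$values) < 1)
  }
})

test_that("latent field variance matches sigma_s^2 over repeated draws", {
  g <- grid_spec(10, 10, 30, -1, 0.045)
  n_seeds <- 200
  fields <- vapply(seq_len(n_seeds), function(s) {
    as.vector(simulate_matern_field(g, rho = 0.3, sigma = 1, seed = s))
  }, numeric(100))
  pixel_var <- apply(fields, 1, var)
  expect_gt(mean(pixel_var), 0.85)
  expect_lt(mean(pixel_var), 1.15)
})

test_that("cluster sizes have the configured mean and range", {
  cfg <- sim_config(grid = grid_spec(12, 12, 30, -1, 0.045),
                    years = 2000, n_clusters = 5000, seed = 6)
  truth <- flat_truth(cfg$grid, 0.3, 2000)
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  cl <- sample_clusters(truth, stack, cfg)
  expect_identical(nrow(cl), 5000L)
  expect_true(all(cl$n_households >= 1 & cl$n_households <= 120))
  expect_gt(mean(cl$n_households), 22)
  expect_lt(mean(cl$n_households), 26)
  # law of large numbers at p = 0.3
  expect_lt(abs(mean(cl$n_electrified / cl$n_households) - 0.3), 0.01)
})

test_that("clusters at saturated pixels are fully electrified", {
  cfg <- sim_config(grid = grid_spec(8, 8, 30, -1, 0.045), years = 2000,
                    n_clusters = 50, seed = 7)
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  truth <- flat_truth(cfg$grid, 1, 2000)
  cl <- sample_clusters(truth, stack, cfg)
  expect_true(all(cl$n_electrified == cl$n_households))
})

test_that("displacement changes only coordinates and flags", {
  w <- tiny_world(dim = 12, n_clusters = 150, seed = 8)
  disp <- displace_clusters(w$clusters, displacement_rule(), seed = 21)
  expect_identical(disp$cluster_id, w$clusters$cluster_id)
  expect_identical(disp$year, w$clusters$year)
  expect_identical(disp$country, w$clusters$country)
  expect_identical(disp$urban, w$clusters$urban)
  expect_identical(disp$n_households, w$clusters$n_households)
  expect_identical(disp$n_electrified, w$clusters$n_electrified)
  expect_true(all(disp$displaced))
  expect_false(any(w$clusters$displaced))
  # double jitter is refused
  expect_error(displace_clusters(disp, displacement_rule(), seed = 1),
               "already displaced")
})

test_that("a zero-distance rule leaves coordinates in place", {
  w <- tiny_world(dim = 10, n_clusters = 50, seed = 9)
  rule <- displacement_rule(0, 0, 0, 0)
  disp <- displace_clusters(w$clusters, rule, seed = 3)
  expect_equal(disp$lon, w$clusters$lon, tolerance = 1e-9)
  expect_equal(disp$lat, w$clusters$lat, tolerance = 1e-9)
  expect_true(all(disp$displaced))
})

test_that("rural far displacements appear at the documented rate", {
  cfg <- sim_config(grid = grid_spec(12, 12, 30, -1, 0.045),
                    years = 2000, n_clusters = 10000,
                    urban_fraction = 0, seed = 10)
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  truth <- flat_truth(cfg$grid, 0.5, 2000)
  cl <- sample_clusters(truth, stack, cfg)
  disp <- displace_clusters(cl, displacement_rule(), seed = 77)
  d_km <- geosphere::distHaversine(cbind(cl$lon, cl$lat),
                                   cbind(disp$lon, disp$lat)) / 1000
  expect_true(all(d_km <= 10 + 1e-9))
  # P(far) * P(U(0,10) > 5) = 0.01 * 0.5 = 0.5%; 99.7% binomial band
  frac_over5 <- mean(d_km > 5)
  expect_gt(frac_over5, 0.0028)
  expect_lt(frac_over5, 0.0072)
})

test_that("population rasters are positive, reproducible and growing", {
  cfg <- sim_config(grid = grid_spec(10, 10, 30, -1, 0.045), seed = 13)
  pop <- generate_population(cfg)
  expect_gt(sum(pop[["2000"]]$values), 0)
  pop2 <- generate_population(cfg)
  expect_identical(pop[["2010"]]$values, pop2[["2010"]]$values)
  totals <- vapply(pop, function(x) sum(x$values), numeric(1))
  expect_true(all(diff(totals) >= 0))
})
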