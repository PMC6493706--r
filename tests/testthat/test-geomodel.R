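test_that("the GMRF precision is symmetric positive definite", {
  g <- grid_spec(8, 8, 0, 0, 0.045)
  Q <- build_matern_precision(g, rho = 0.2, sigma_s = 0.8)
  Qd <- as.matrix(Q)
  expect_equal(Qd, t(Qd))
  expect_gt(min(eigen(Qd, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(build_matern_precision(g, -0.1, 1))
  expect_error(build_matern_precision(g, 0.2, 0))
})

test_that("GMRF correlation decays with distance from an interior node", {
  g <- grid_spec(20, 20, 0, 0, 0.045)
  Q <- build_matern_precision(g, rho = 0.25, sigma_s = 1)
  Si <- as.matrix(Matrix::solve(Q))
  ctr <- (10 - 1) * 20 + 10  # column-major index of node (10, 10)
  along_row <- (seq(10, 16) - 1) * 20 + 10
  corr <- Si[ctr, along_row] / sqrt(Si[ctr, ctr] * diag(Si)[along_row])
  expect_true(all(diff(corr) < 0))
})

test_that("M1 matches the iteratively reweighted GLM oracle", {
  for (seed in c(21, 22)) {
    w <- tiny_world(dim = 14, n_clusters = 350, seed = seed)
    f1 <- fit_model(model_spec("M1"), w$obs)
    X <- cbind(1, w$obs$ntl / 63,
               sapply(setdiff(sort(unique(w$obs$lulc)), 2),
                      function(cat) as.numeric(w$obs$lulc == cat)),
               w$obs$iap, w$obs$pia)
    oracle <- glm(cbind(w$obs$k, w$obs$n - w$obs$k) ~ X - 1,
                  family = binomial())
    expect_lt(max(abs(f1$beta_mean - unname(coef(oracle)))), 1e-6)
  }
})

test_that("an all-negative response drives predictions to zero", {
  w <- tiny_world(dim = 10, n_clusters = 150, seed = 23)
  obs0 <- w$obs
  obs0$k <- 0L
  f0 <- fit_model(model_spec("M1"), obs0)
  expect_lt(f0$beta_mean[["(Intercept)"]], -5)
  pred <- predict_surface(f0, w$stack, w$cfg$years[1])
  expect_lt(max(pred$values, na.rm = TRUE), 0.01)
})

test_that("M1 predictions equal the hand-computed inverse logit", {
  w <- tiny_world(dim = 12, n_clusters = 250, seed = 24)
  f1 <- fit_model(model_spec("M1"), w$obs)
  yr <- w$cfg$years[1]
  pred <- predict_surface(f1, w$stack, yr)
  lay <- w$stack$layers[[as.character(yr)]]
  set.seed(1)
  for (px in sample(144, 10)) {
    r <- (px - 1) %% 12 + 1; c2 <- (px - 1) %/% 12 + 1
    x <- c(1, lay$ntl$values[r, c2] / 63,
           as.numeric(lay$lulc$values[r, c2] ==
                        f1$design$lulc_levels),
           lay$iap$values[r, c2], lay$pia$values[r, c2])
    expect_equal(pred$values[r, c2],
                 plogis(sum(x * f1$beta_mean)), tolerance = 1e-12)
  }
})

test_that("M2 converges to M1 as the field variance vanishes", {
  w <- tiny_world(dim = 12, n_clusters = 250, seed = 25)
  f1 <- fit_model(model_spec("M1"), w$obs)
  f2 <- fit_model(model_spec("M2"), w$obs, grid = w$cfg$grid,
                  hyper_fixed = c(rho = 0.3, sigma_s = 1e-3),
                  field_sd = FALSE)
  p1 <- predict_surface(f1, w$stack, w$cfg$years[1])
  p2 <- predict_surface(f2, w$stack, w$cfg$years[1])
  expect_lt(max(abs(p1$values - p2$values), na.rm = TRUE), 0.01)
})

test_that("fits are deterministic and the outer objective is monotone", {
  w <- tiny_world(dim = 12, n_clusters = 200, seed = 26)
  fa <- fit_model(model_spec("M2"), w$obs, grid = w$cfg$grid,
                  field_sd = FALSE)
  fb <- fit_model(model_spec("M2"), w$obs, grid = w$cfg$grid,
                  field_sd = FALSE)
  expect_identical(fa$beta_mean, fb$beta_mean)
  expect_identical(fa$rho_hat, fb$rho_hat)
  expect_identical(fa$field_mean, fb$field_mean)
  expect_identical(fa$cpo, fb$cpo)
  expect_false(is.unsorted(fa$objective_trace))
})

test_that("rank-deficient designs are rejected naming the column", {
  w <- tiny_world(dim = 10, n_clusters = 150, seed = 27)
  obs <- w$obs
  obs$pia <- obs$iap  # perfectly collinear
  expect_error(fit_model(model_spec("M1"), obs), "pia")
})

test_that("M4 fits a coupled field per year and guards its support", {
  w <- tiny_world(dim = 10, years = c(2000, 2006, 2013),
                  n_clusters = 250, seed = 28)
  f4 <- fit_model(model_spec("M4"), w$obs, grid = w$cfg$grid,
                  field_sd = FALSE)
  expect_identical(names(f4$field_mean), c("2000", "2006", "2013"))
  expect_true(abs(f4$ar1_hat) < 1)
  p <- predict_surface(f4, w$stack, 2006)
  expect_true(all(p$values > 0 & p$values < 1, na.rm = TRUE))
  expect_error(predict_surface(f4, w$stack, 2013 + 0), NA)
  # 2001 has covariates in a 14-year stack but no fitted field
  expect_error(
    predict_surface(f4, covariate_stack(w$cfg$grid, list(
      "2001" = w$stack$layers[["2000"]])), 2001),
    "support")
})

test_that("field posterior sd is returned at grid nodes when requested", {
  w <- tiny_world(dim = 10, n_clusters = 200, seed = 29)
  f2 <- fit_model(model_spec("M2"), w$obs, grid = w$cfg$grid,
                  field_sd = TRUE)
  expect_identical(dim(f2$field_sd), c(10L, 10L))
  expect_true(all(f2$field_sd > 0))
  # nodes carrying observations are better constrained than the corners
  expect_lt(min(f2$field_sd), max(f2$field_sd))
})

test_that("classification is strict at the threshold and keeps nodata", {
  g <- grid_spec(1, 4, 0, 0, 0.045)
  p <- raster_layer(matrix(c(0.5, 0.6, 0.4, NA), 1, 4), g,
                    kind = "probability")
  cls <- classify_surface(p, 0.5)
  expect_equal(cls$values[1, 1:3], c(0, 1, 0))
  expect_true(is.na(cls$values[1, 4]))
  expect_error(classify_surface(p, 1.2), "threshold")
  expect_error(classify_surface(cls, 0.5), "probability")
})

test_that("misuse of the fitting interface errors early", {
  w <- tiny_world(dim = 10, n_clusters = 100, seed = 30)
  expect_error(fit_model(model_spec("M2"), w$obs), "grid")
  expect_error(fit_model(model_spec("M1"), w$obs[0, ]), "empty")
})
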