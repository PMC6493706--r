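#' Candidate model specification
#'
#' The four candidate binomial models share the fixed effects (intercept,
#' scaled nighttime lights, land-cover dummies with low biomass as the
#' reference, IAP, PIA) and differ in their structure:
#' \describe{
#'   \item{M1}{fixed effects only (logistic-binomial GLM);}
#'   \item{M2}{adds one Matern (nu = 1) spatial random effect on the grid;}
#'   \item{M3}{as M2 plus year as a fixed effect;}
#'   \item{M4}{replaces the spatial effect and the year term by a
#'     spatiotemporal random effect (one field per year, first-order
#'     autoregressive coupling).}
#' }
#'
#' @param variant One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param year_effect `"linear"` (year centred mid-window, scaled to
#'   \[-1, 1\]) or `"factor"` (per-year dummies); M3 only.
#' @param priors List of hyperprior settings: `alpha_rho` (prior mass below
#'   the median range `rho0`, default 0.5 at half the domain width),
#'   `sigma0`/`alpha_sigma` (P(sigma_s > sigma0) = alpha_sigma, defaults
#'   1 and 0.1). `rho0 = NULL` means half the domain width.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = c("M1", "M2", "M3", "M4"),
                       year_effect = c("linear", "factor"),
                       priors = list(rho0 = NULL, sigma0 = 1,
                                     alpha_sigma = 0.1)) {
  variant <- match.arg(variant)
  year_effect <- match.arg(year_effect)
  structure(list(variant = variant, year_effect = year_effect,
                 priors = priors),
            class = "model_spec")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

binom_loglik <- function(k, n, eta) {
  sum(k * eta - n * log1pexp(eta) + lchoose(n, k))
}

#' Sparse Matern (nu = 1) precision on a regular grid
#'
#' Gaussian Markov random field approximation of a Matern field with
#' smoothness 1, built from the five-point-stencil discretisation of the
#' operator \eqn{(\kappa^2 - \Delta)} with Neumann boundaries:
#' \eqn{Q = \tau^2 (\kappa^2 M + G) M^{-1} (\kappa^2 M + G)} with lumped
#' mass \eqn{M = h^2 I}, graph-Laplacian stiffness `G`,
#' \eqn{\kappa = \sqrt{8}/\rho} (correlation approximately 0.13 at distance
#' `rho`) and \eqn{\tau^2 = 1/(4\pi\kappa^2\sigma_s^2)} so the implied
#' marginal standard deviation away from the boundary approximates
#' `sigma_s`.
#'
#' @param grid A [grid_spec()].
#' @param rho Range in degrees (> 0).
#' @param sigma_s Marginal standard deviation (> 0).
#' @return Sparse symmetric positive-definite precision matrix
#'   (`Matrix::dsCMatrix`) over the grid nodes in column-major order.
#' @export
build_matern_precision <- function(grid, rho, sigma_s) {
  stopifnot(rho > 0, sigma_s > 0)
  nr <- grid$nrow; nc <- grid$ncol
  n <- nr * nc
  h <- grid$cellsize
  idx <- seq_len(n)
  vert <- idx[(idx - 1L) %% nr + 1L < nr]          # neighbour below
  horiz <- idx[idx <= n - nr]                      # neighbour east
  ii <- c(vert, horiz)
  jj <- c(vert + 1L, horiz + nr)
  Adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n))
  deg <- Matrix::rowSums(Adj)
  G <- Matrix::Diagonal(n, deg) - Adj
  kappa <- sqrt(8) / rho
  K <- kappa^2 * h^2 * Matrix::Diagonal(n) + G
  tau2 <- 1 / (4 * pi * kappa^2 * sigma_s^2)
  Q <- Matrix::forceSymmetric((tau2 / h^2) * (K %*% K))
  as(Q, "CsparseMatrix")
}

# AR(1) precision with unit marginal variance
ar1_precision <- function(T, a) {
  if (T == 1) return(Matrix::Diagonal(1))
  d <- c(1, rep(1 + a^2, T - 2), 1) / (1 - a^2)
  off <- rep(-a / (1 - a^2), T - 1)
  Matrix::bandSparse(T, k = c(0, 1), diagonals = list(d, off),
                     symmetric = TRUE)
}

# design matrix on the model scale; lulc dummy-coded with category 2
# (low biomass) as reference, ntl scaled by 1/63, year centred and scaled
build_design <- function(obs, variant, year_effect = "linear",
                         lulc_levels = NULL, year_range = NULL,
                         year_levels_fixed = NULL) {
  X <- cbind(`(Intercept)` = 1, ntl = obs$ntl / 63)
  if (is.null(lulc_levels)) {
    cats <- sort(unique(obs$lulc))
    # low biomass (2) is the reference; if a small landscape lacks it
    # entirely, fall back to the lowest present category to keep the
    # dummies and intercept jointly full rank
    ref <- if (2 %in% cats) 2 else cats[1]
    lulc_levels <- setdiff(cats, ref)
  }
  for (cat in lulc_levels) {
    X <- cbind(X, as.numeric(obs$lulc == cat))
    colnames(X)[ncol(X)] <- paste0("lulc", cat)
  }
  X <- cbind(X, iap = obs$iap, pia = obs$pia)
  if (is.null(year_range)) year_range <- range(obs$year)
  year_levels <- NULL
  if (variant == "M3") {
    if (year_effect == "linear") {
      X <- cbind(X, year = scale_year(obs$year, year_range))
    } else {
      year_levels <- if (!is.null(year_levels_fixed)) year_levels_fixed
        else sort(unique(obs$year))
      for (t in year_levels[-1]) {
        X <- cbind(X, as.numeric(obs$year == t))
        colnames(X)[ncol(X)] <- paste0("year", t)
      }
    }
  }
  list(X = X, lulc_levels = lulc_levels, year_range = year_range,
       year_effect = year_effect, year_levels = year_levels)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# scale rows of a sparse dgCMatrix: returns W A with W = diag(w)
row_scale <- function(A, w) {
  A@x <- A@x * w[A@i + 1L]
  A
}

# Newton maximisation of the joint log posterior at fixed prior precision.
# A: sparse n_obs x m map to the linear predictor; Qu: m x m prior precision
inner_newton <- function(k, n, A, Qu, u0 = NULL, maxit = 100,
                         tol = 1e-8, chol_cache = NULL) {
  m <- ncol(A)
  u <- if (is.null(u0)) numeric(m) else u0
  negpost <- function(u, eta) {
    -(sum(k * eta - n * log1pexp(eta))) +
      0.5 * sum(u * as.numeric(Qu %*% u))
  }
  eta <- as.numeric(A %*% u)
  f <- negpost(u, eta)
  ch <- chol_cache
  grad_norm <- Inf
  for (it in seq_len(maxit)) {
    p <- plogis(eta)
    g <- as.numeric(Matrix::crossprod(A, k - n * p)) -
      as.numeric(Qu %*% u)
    grad_norm <- max(abs(g))
    if (grad_norm < tol) break
    w <- pmax(n * p * (1 - p), 1e-12)
    H <- Matrix::forceSymmetric(Matrix::crossprod(A, row_scale(A, w)) + Qu)
    ch <- tryCatch({
      if (is.null(ch)) Matrix::Cholesky(H, LDL = FALSE)
      else Matrix::update(ch, H)
    }, error = function(e) {
      Matrix::Cholesky(Matrix::forceSymmetric(
        H + Matrix::Diagonal(m, 1e-8)), LDL = FALSE)
    })
    delta <- as.numeric(as.matrix(Matrix::solve(ch, g)))
    step <- 1
    repeat {
      u_new <- u + step * delta
      eta_new <- as.numeric(A %*% u_new)
      f_new <- negpost(u_new, eta_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      step <- step / 2
      if (step < 1e-12) { u_new <- u; eta_new <- eta; f_new <- f; break }
    }
    if (abs(f - f_new) < 1e-12 && step < 1e-12) break
    u <- u_new; eta <- eta_new; f <- f_new
  }
  p <- plogis(eta)
  w <- pmax(n * p * (1 - p), 1e-12)
  H <- Matrix::forceSymmetric(Matrix::crossprod(A, row_scale(A, w)) + Qu)
  ch <- tryCatch({
    if (is.null(ch)) Matrix::Cholesky(H, LDL = FALSE)
    else Matrix::update(ch, H)
  }, error = function(e) {
    Matrix::Cholesky(Matrix::forceSymmetric(
      H + Matrix::Diagonal(m, 1e-8)), LDL = FALSE)
  })
  list(u = u, eta = eta, ch = ch, H = H, grad_norm = grad_norm,
       iterations = it, loglik = binom_loglik(k, n, eta),
       quad = sum(u * as.numeric(Qu %*% u)))
}

# log determinant of the matrix factored by a CHMfactor
chol_logdet <- function(ch) {
  as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                 sqrt = FALSE)$modulus)
}

# hyperprior log densities on the optimisation scale (incl. Jacobians)
log_hyperprior <- function(theta, rho0, sigma0 = 1, alpha_sigma = 0.1) {
  rho <- exp(theta[1]); sigma <- exp(theta[2])
  lambda_r <- rho0 * log(2)
  lambda_s <- -log(alpha_sigma) / sigma0
  lp <- (log(lambda_r) - 2 * log(rho) - lambda_r / rho + log(rho)) +
    (log(lambda_s) - lambda_s * sigma + log(sigma))
  if (length(theta) >= 3) {
    a <- tanh(theta[3])
    lp <- lp + log1p(-a^2) - log(2)   # uniform(-1,1) + atanh Jacobian
  }
  lp
}

#' Fit a candidate model by Laplace approximation
#'
#' Maximises the joint posterior of the latent field and fixed effects by
#' Newton iteration at fixed hyperparameters (the fixed effects carry a
#' flat prior), and optimises the Laplace-approximated log marginal
#' posterior over `(log rho, log sigma_s)` (plus the autoregressive
#' correlation for M4) by Nelder-Mead. The fit is deterministic: fixed
#' starting values, no randomness.
#'
#' @param spec A [model_spec()].
#' @param obs An observation table (see [extract_buffer_covariates()]).
#' @param grid The latent-field [grid_spec()]; required for M2-M4.
#' @param hyper_fixed Optional named vector `c(rho =, sigma_s =)` (and
#'   `ar1 =` for M4) to skip hyperparameter optimisation.
#' @param field_sd Compute posterior standard deviations of the latent
#'   field nodes (moderately expensive); the fixed-effect standard errors
#'   are always computed.
#' @param control List overriding `maxit_inner` (100), `tol_grad` (1e-8),
#'   `maxit_outer` (200), `reltol_outer` (1e-6), `gh_points` (32).
#' @return An object of class `mbg_fit`: posterior summaries of the fixed
#'   effects, hyperparameter estimates, latent field mean (and optionally
#'   sd), per-observation linear-predictor moments and CPO values, the
#'   log-likelihood and Laplace log marginal at the mode, convergence
#'   diagnostics and the design metadata needed for prediction.
#' @export
fit_model <- function(spec, obs, grid = NULL, hyper_fixed = NULL,
                      field_sd = TRUE, control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(obs) == 0) stop("observation table is empty")
  ctl <- modifyList(list(maxit_inner = 100, tol_grad = 1e-8,
                         maxit_outer = 200, reltol_outer = 1e-6,
                         gh_points = 32), control)
  variant <- spec$variant
  des <- build_design(obs, variant, spec$year_effect)
  X <- des$X
  check_full_rank(X)
  p <- ncol(X)
  k <- obs$k; nn <- obs$n
  Xs <- as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")

  if (variant == "M1") {
    Qu <- Matrix::Diagonal(p, 1e-8)
    fitin <- inner_newton(k, nn, Xs, Qu, maxit = ctl$maxit_inner,
                          tol = ctl$tol_grad)
    if (fitin$grad_norm > 1e-4) {
      stop(sprintf(
        "M1 Newton did not converge: gradient norm %.3g after %d iterations",
        fitin$grad_norm, fitin$iterations))
    }
    Hinv_cols <- as.matrix(Matrix::solve(fitin$ch, diag(p)))
    beta_sd <- sqrt(diag(Hinv_cols))
    S2 <- as.matrix(Matrix::solve(fitin$ch, Matrix::t(Xs)))
    eta_var <- colSums(as.matrix(Matrix::t(Xs)) * S2)
    fit <- list(
      variant = variant, beta_mean = setNames(fitin$u, colnames(X)),
      beta_sd = setNames(beta_sd, colnames(X)),
      rho_hat = NA_real_, sigma_s_hat = 0, ar1_hat = NA_real_,
      field_mean = NULL, field_sd = NULL,
      loglik = fitin$loglik, logml = fitin$loglik,
      eta_mean = fitin$eta, eta_var = eta_var,
      iterations = fitin$iterations, grad_norm = fitin$grad_norm,
      converged = TRUE, objective_trace = fitin$loglik,
      design = des[c("lulc_levels", "year_range", "year_effect",
                     "year_levels")],
      grid = grid, years = sort(unique(obs$year)), spec = spec,
      beta_cov = Hinv_cols,
      internals = list(ch = fitin$ch, m_lat = 0L, p = p,
                       s_hat = numeric(0)))
    fit$cpo <- cpo_fast(fit$eta_mean, fit$eta_var, k, nn, ctl$gh_points)
    class(fit) <- "mbg_fit"
    return(fit)
  }

  if (is.null(grid)) stop("grid is required for variants M2-M4")
  cells <- point_to_cell(grid, obs$lon, obs$lat)
  if (anyNA(cells$row)) {
    stop(sum(is.na(cells$row)), " observation(s) fall outside the grid")
  }
  ng <- grid$nrow * grid$ncol
  years <- sort(unique(obs$year))
  Tt <- length(years)
  cell_i <- cell_index(grid, cells$row, cells$col)
  if (variant == "M4") {
    t_i <- match(obs$year, years)
    lat_i <- (t_i - 1L) * ng + cell_i
    m_lat <- ng * Tt
  } else {
    lat_i <- cell_i
    m_lat <- ng
  }
  n_obs <- nrow(obs)
  A_s <- Matrix::sparseMatrix(i = seq_len(n_obs), j = lat_i, x = 1,
                              dims = c(n_obs, m_lat))
  A <- cbind(A_s, Xs)
  m <- m_lat + p

  width <- max(grid_xmax(grid) - grid$xll, grid_ytop(grid) - grid$yll)
  rho0 <- if (!is.null(spec$priors$rho0)) spec$priors$rho0 else width / 2
  sigma0 <- if (!is.null(spec$priors$sigma0)) spec$priors$sigma0 else 1
  alpha_sigma <- if (!is.null(spec$priors$alpha_sigma))
    spec$priors$alpha_sigma else 0.1

  make_Qu <- function(theta) {
    rho <- exp(theta[1]); sigma <- exp(theta[2])
    Qs <- build_matern_precision(grid, rho, sigma)
    if (variant == "M4") {
      a <- tanh(theta[3])
      Qt <- ar1_precision(Tt, a)
      Qlat <- Matrix::forceSymmetric(Matrix::kronecker(Qt, Qs))
      ldet <- ng * as.numeric(Matrix::determinant(
        Qt, logarithm = TRUE)$modulus) +
        Tt * chol_logdet(Matrix::Cholesky(Qs, LDL = FALSE))
    } else {
      Qlat <- Qs
      ldet <- chol_logdet(Matrix::Cholesky(Qs, LDL = FALSE))
    }
    Qu <- Matrix::bdiag(Qlat, Matrix::Diagonal(p, 1e-8))
    list(Qu = as(Matrix::forceSymmetric(Qu), "CsparseMatrix"), ldet = ldet)
  }

  env <- new.env()
  env$u_warm <- NULL
  env$ch <- NULL
  env$trace <- numeric(0)
  outer_fn <- function(theta) {
    Qs <- make_Qu(theta)
    fi <- inner_newton(k, nn, A, Qs$Qu, u0 = env$u_warm,
                       maxit = ctl$maxit_inner, tol = ctl$tol_grad,
                       chol_cache = env$ch)
    env$u_warm <- fi$u
    env$ch <- fi$ch
    lml <- fi$loglik - 0.5 * fi$quad + 0.5 * Qs$ldet -
      0.5 * chol_logdet(fi$ch)
    obj <- lml + log_hyperprior(theta, rho0, sigma0, alpha_sigma)
    best <- if (length(env$trace)) max(env$trace[length(env$trace)], obj)
      else obj
    env$trace <- c(env$trace, best)
    -obj
  }

  theta0 <- c(log(width / 5), log(0.5))
  if (variant == "M4") theta0 <- c(theta0, atanh(0.5))
  if (!is.null(hyper_fixed)) {
    theta_hat <- c(log(hyper_fixed[["rho"]]),
                   log(hyper_fixed[["sigma_s"]]))
    if (variant == "M4") theta_hat <- c(theta_hat,
                                        atanh(hyper_fixed[["ar1"]]))
    outer_fn(theta_hat)
    opt_conv <- 0L
  } else {
    opt <- stats::optim(theta0, outer_fn, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit_outer,
                                       reltol = ctl$reltol_outer))
    theta_hat <- opt$par
    opt_conv <- opt$convergence
  }

  Qs <- make_Qu(theta_hat)
  fi <- inner_newton(k, nn, A, Qs$Qu, u0 = env$u_warm,
                     maxit = ctl$maxit_inner, tol = ctl$tol_grad,
                     chol_cache = env$ch)
  if (fi$grad_norm > 1e-4) {
    stop(sprintf(
      "inner Newton did not converge: gradient norm %.3g after %d iterations",
      fi$grad_norm, fi$iterations))
  }
  lml <- fi$loglik - 0.5 * fi$quad + 0.5 * Qs$ldet -
    0.5 * chol_logdet(fi$ch)

  beta_idx <- m_lat + seq_len(p)
  Eb <- Matrix::sparseMatrix(i = beta_idx, j = seq_len(p), x = 1,
                             dims = c(m, p))
  Sb <- as.matrix(Matrix::solve(fi$ch, Eb))
  beta_sd <- sqrt(Sb[cbind(beta_idx, seq_len(p))])
  tA <- Matrix::t(A)
  Sa <- as.matrix(Matrix::solve(fi$ch, tA))
  eta_var <- as.numeric(Matrix::colSums(tA * Sa))

  s_hat <- fi$u[seq_len(m_lat)]
  if (variant == "M4") {
    field_mean <- lapply(seq_len(Tt), function(t) {
      matrix(s_hat[(t - 1) * ng + seq_len(ng)], grid$nrow, grid$ncol)
    })
    names(field_mean) <- as.character(years)
  } else {
    field_mean <- matrix(s_hat, grid$nrow, grid$ncol)
  }
  fsd <- NULL
  if (isTRUE(field_sd)) {
    dvar <- numeric(m_lat)
    chunk <- 500L
    for (s0 in seq(1L, m_lat, by = chunk)) {
      e0 <- min(m_lat, s0 + chunk - 1L)
      E <- Matrix::sparseMatrix(i = s0:e0, j = seq_len(e0 - s0 + 1L),
                                x = 1, dims = c(m, e0 - s0 + 1L))
      S <- as.matrix(Matrix::solve(fi$ch, E))
      dvar[s0:e0] <- S[cbind(s0:e0, seq_len(e0 - s0 + 1L))]
    }
    if (variant == "M4") {
      fsd <- lapply(seq_len(Tt), function(t) {
        matrix(sqrt(dvar[(t - 1) * ng + seq_len(ng)]),
               grid$nrow, grid$ncol)
      })
      names(fsd) <- as.character(years)
    } else {
      fsd <- matrix(sqrt(dvar), grid$nrow, grid$ncol)
    }
  }

  fit <- list(
    variant = variant,
    beta_mean = setNames(fi$u[beta_idx], colnames(X)),
    beta_sd = setNames(beta_sd, colnames(X)),
    rho_hat = exp(theta_hat[1]), sigma_s_hat = exp(theta_hat[2]),
    ar1_hat = if (variant == "M4") tanh(theta_hat[3]) else NA_real_,
    field_mean = field_mean, field_sd = fsd,
    loglik = fi$loglik, logml = lml,
    eta_mean = fi$eta, eta_var = eta_var,
    iterations = fi$iterations, grad_norm = fi$grad_norm,
    converged = (opt_conv == 0L),
    objective_trace = env$trace,
    design = des[c("lulc_levels", "year_range", "year_effect",
                   "year_levels")],
    grid = grid, years = years, spec = spec,
    internals = list(ch = fi$ch, m_lat = m_lat, p = p, s_hat = s_hat))
  fit$cpo <- cpo_fast(fit$eta_mean, fit$eta_var, k, nn, ctl$gh_points)
  class(fit) <- "mbg_fit"
  fit
}

#' @export
#' @method print mbg_fit
print.mbg_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d fixed effects, log marginal %.2f\n",
              x$variant, length(x$beta_mean), x$logml))
  est <- cbind(estimate = x$beta_mean, sd = x$beta_sd)
  print(round(est, 4))
  if (x$variant != "M1") {
    cat(sprintf("range rho = %.3f deg, field sd sigma_s = %.3f\n",
                x$rho_hat, x$sigma_s_hat))
    if (x$variant == "M4") cat(sprintf("AR(1) correlation = %.3f\n",
                                       x$ar1_hat))
  }
  invisible(x)
}

# design matrix for one year's grid pixels using a fit's design metadata
grid_design <- function(fit, layers, year) {
  ntl <- as.vector(layers$ntl$values) / 63
  lulc <- as.vector(layers$lulc$values)
  iap <- as.vector(layers$iap$values)
  pia <- as.vector(layers$pia$values)
  X <- cbind(`(Intercept)` = 1, ntl = ntl)
  for (cat in fit$design$lulc_levels) {
    X <- cbind(X, as.numeric(lulc == cat))
    colnames(X)[ncol(X)] <- paste0("lulc", cat)
  }
  X <- cbind(X, iap = iap, pia = pia)
  if (fit$variant == "M3") {
    if (fit$design$year_effect == "linear") {
      X <- cbind(X, year = scale_year(rep(year, length(ntl)),
                                      fit$design$year_range))
    } else {
      for (t in fit$design$year_levels[-1]) {
        X <- cbind(X, as.numeric(year == t))
        colnames(X)[ncol(X)] <- paste0("year", t)
      }
    }
  }
  X
}

#' Predict the probability surface for one year
#'
#' Per pixel, \eqn{p = \mathrm{logit}^{-1}(x'\hat\beta + \hat S)} using the
#' posterior means; covariate nodata propagates to the output. For M4 the
#' requested year must be one of the fitted years.
#'
#' @param fit An [fit_model()] result.
#' @param stack A [covariate_stack()] covering `year`.
#' @param year Prediction year.
#' @return A `probability` [raster_layer()].
#' @export
predict_surface <- function(fit, stack, year) {
  stopifnot(inherits(fit, "mbg_fit"), inherits(stack, "covariate_stack"))
  lay <- stack$layers[[as.character(year)]]
  if (is.null(lay)) stop("covariate stack has no layers for year ", year)
  g <- stack$grid
  X <- grid_design(fit, lay, year)
  eta <- drop(X %*% fit$beta_mean[colnames(X)])
  if (fit$variant %in% c("M2", "M3")) {
    if (!same_grid(fit$grid, g)) stop("stack grid differs from fit grid")
    eta <- eta + as.vector(fit$field_mean)
  } else if (fit$variant == "M4") {
    if (!same_grid(fit$grid, g)) stop("stack grid differs from fit grid")
    if (!as.character(year) %in% names(fit$field_mean)) {
      stop("year ", year, " outside the M4 fit's support")
    }
    eta <- eta + as.vector(fit$field_mean[[as.character(year)]])
  }
  raster_layer(matrix(plogis(eta), g$nrow, g$ncol), g,
               kind = "probability")
}

#' Threshold a probability surface into access classes
#'
#' Pixels with probability strictly above the threshold are classified 1
#' (electricity), others 0; nodata is preserved.
#'
#' @param surface A `probability` [raster_layer()].
#' @param threshold Classification threshold in (0, 1), default 0.5.
#' @return A `binary` [raster_layer()].
#' @export
classify_surface <- function(surface, threshold = 0.5) {
  stopifnot(inherits(surface, "raster_layer"))
  if (surface$kind != "probability") {
    stop("classify_surface expects a probability layer")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be inside (0, 1)")
  }
  v <- surface$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v > threshold))
  raster_layer(out, surface$grid, kind = "binary")
}
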