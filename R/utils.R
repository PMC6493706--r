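# Kilometres per degree of latitude (spherical mean radius).
KM_PER_DEG <- 111.32

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package operations do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gauss-Hermite quadrature nodes and weights
#'
#' Golub-Welsch construction from the Jacobi matrix of the (physicists')
#' Hermite polynomials; used for deterministic one-dimensional Gaussian
#' expectations in the CPO computations.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights` such that
#'   `sum(weights * f(nodes)) ~ integral f(x) exp(-x^2) dx`.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Great-circle destination point on the sphere used by the haversine
# distance (radius 6378137 m): the haversine distance from (lon, lat) to
# the returned point equals dist_m to machine precision.
dest_point <- function(lon, lat, bearing_deg, dist_m, r = 6378137) {
  phi1 <- lat * pi / 180
  lam1 <- lon * pi / 180
  theta <- bearing_deg * pi / 180
  delta <- dist_m / r
  phi2 <- asin(sin(phi1) * cos(delta) +
                 cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  cbind(lon = lam2 * 180 / pi, lat = phi2 * 180 / pi)
}

# Expectation E[g(eta)] for eta ~ N(m, v) by Gauss-Hermite; g acts on a vector
# of eta values and returns log g. Returns log E[g].
gh_log_expectation <- function(log_g, m, v, gh) {
  eta <- m + sqrt(2 * max(v, 0)) * gh$nodes
  logsumexp(log(gh$weights / sqrt(pi)) + log_g(eta))
}
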