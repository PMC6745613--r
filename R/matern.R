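#' Matern parameter bundle
#'
#' Marginal variance `sigma2_eta`, scale `kappa` and smoothness `nu` (fixed at
#' 1 throughout the package) of the stationary Matern field on the prediction
#' grid. The practical range is `r = sqrt(8 nu) / kappa`, the distance at
#' which correlation has dropped to about 0.14.
#'
#' @param sigma2_eta marginal variance (> 0).
#' @param kappa scale parameter (> 0).
#' @param nu smoothness (> 0); only `nu = 1` is supported by the SPDE form.
#' @return An object of class `matern_params` with a derived `range` element.
#' @export
matern_params <- function(sigma2_eta = 1, kappa = sqrt(8), nu = 1) {
  if (sigma2_eta < 0) stopf("sigma2_eta must be nonnegative")
  if (kappa <= 0 || nu <= 0) stopf("kappa and nu must be positive")
  structure(list(sigma2_eta = sigma2_eta, kappa = kappa, nu = nu,
                 range = kappa_to_range(kappa, nu)),
            class = "matern_params")
}

#' Convert between Matern range and scale
#'
#' `range_to_kappa()` returns `kappa = sqrt(8 nu) / r`;
#' `kappa_to_range()` is its inverse. With `nu = 1`, ranges 0.3, 0.5 and 0.7
#' on the unit square give kappa 9.4, 5.7 and 4.0 (to one decimal).
#'
#' @param r practical range (> 0).
#' @param kappa scale parameter (> 0).
#' @param nu smoothness (> 0).
#' @return The implied scale (or range).
#' @examples
#' round(range_to_kappa(0.3), 1)  # 9.4
#' @export
range_to_kappa <- function(r, nu = 1) {
  if (any(r <= 0) || nu <= 0) stopf("r and nu must be positive")
  sqrt(8 * nu) / r
}

#' @rdname range_to_kappa
#' @export
kappa_to_range <- function(kappa, nu = 1) {
  if (any(kappa <= 0) || nu <= 0) stopf("kappa and nu must be positive")
  sqrt(8 * nu) / kappa
}

#' Matern covariance matrix
#'
#' Evaluates `sigma2 * 2^(1-nu)/Gamma(nu) * (kappa d)^nu K_nu(kappa d)` over a
#' pairwise distance matrix, with the limiting value `sigma2` on the diagonal
#' (zero distance).
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param params a [matern_params()].
#' @return Covariance matrix of the same dimension as `D`.
#' @export
matern_cov <- function(D, params) {
  D <- as.matrix(D)
  if (any(D < 0)) stopf("distances must be nonnegative")
  out <- matern_correlation(D, params$kappa, params$nu) * params$sigma2_eta
  out
}

matern_correlation <- function(d, kappa, nu = 1) {
  out <- d
  pos <- d > 0
  kd <- kappa * d[pos]
  out[pos] <- 2^(1 - nu) / gamma(nu) * kd^nu * besselK(kd, nu)
  out[!pos] <- 1
  ## besselK underflows to 0 for very large kd, which is the correct limit
  out[is.na(out)] <- 0
  out
}

#' Reusable sampler for a dense Matern Gaussian process
#'
#' Factorizes the exact Matern covariance of a point set once so repeated
#' draws (e.g. across simulation replicates) reuse the Cholesky factor. A
#' jitter ladder `1e-10 ... 1e-6` (relative to `sigma2_eta`) is applied if the
#' covariance is numerically rank-deficient.
#'
#' @param points n x 2 coordinate matrix (or a [grid_domain()]).
#' @param params a [matern_params()].
#' @return A function `(n_draws = 1)` returning an n x n_draws matrix of
#'   draws, consuming `n * n_draws` standard normals from the RNG stream.
#' @export
gp_sampler <- function(points, params) {
  pts <- if (inherits(points, "grid_domain")) points$points else as.matrix(points)
  n <- nrow(pts)
  if (params$sigma2_eta == 0) {
    return(function(n_draws = 1) matrix(0, n, n_draws))
  }
  S <- matern_cov(as.matrix(dist(pts)), params)
  R <- NULL
  for (jit in c(0, 10^seq(-10, -6))) {
    Sj <- S
    if (jit > 0) diag(Sj) <- diag(Sj) + jit * params$sigma2_eta
    R <- tryCatch(chol(Sj), error = function(e) NULL)
    if (!is.null(R)) break
  }
  if (is.null(R)) stopf("covariance factorization failed even with jitter")
  function(n_draws = 1) {
    z <- matrix(rnorm(n * n_draws), n, n_draws)
    crossprod(R, z)
  }
}

#' Draw a Matern Gaussian process on a grid
#'
#' One seeded draw of the grid-level spatial field `eta ~ N(0, Sigma)` with
#' exact dense Matern covariance. For repeated draws over the same point set
#' use [gp_sampler()].
#'
#' @param grid a [grid_domain()] or coordinate matrix.
#' @param params a [matern_params()].
#' @param seed optional integer seed.
#' @return Numeric vector of field values at the grid points.
#' @export
sample_gp <- function(grid, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop(gp_sampler(grid, params)(1))
}
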