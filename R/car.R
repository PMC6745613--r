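#' Leroux CAR parameter bundle
#'
#' Variance `sigma2_phi` and spatial autocorrelation `rho` of the areal-level
#' conditional autoregressive field, `phi ~ N(0, sigma2_phi * Q(W)^-1)` with
#' the Leroux precision `Q(W) = rho (diag(W 1) - W) + (1 - rho) I`. The field
#' interpolates between independence (`rho = 0`) and the intrinsic CAR
#' (`rho = 1`, singular).
#'
#' @param sigma2_phi variance (> 0).
#' @param rho autocorrelation in `[0, 1)`.
#' @return An object of class `leroux_params`.
#' @export
leroux_params <- function(sigma2_phi = 1, rho = 0.6) {
  if (sigma2_phi < 0) stopf("sigma2_phi must be nonnegative")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  structure(list(sigma2_phi = sigma2_phi, rho = rho), class = "leroux_params")
}

#' Leroux CAR precision matrix
#'
#' `Q(W) = rho * (diag(W 1) - W) + (1 - rho) * I`, positive definite for
#' `rho < 1` (its eigenvalues are bounded below by `1 - rho`).
#'
#' @param W binary symmetric adjacency matrix with zero diagonal.
#' @param rho autocorrelation in `[0, 1]`.
#' @param sparse return a `Matrix` sparse matrix (default) or base matrix.
#' @return The nA x nA precision matrix (unit variance scale).
#' @export
leroux_precision <- function(W, rho, sparse = TRUE) {
  W <- as.matrix(W)
  if (!isSymmetric(unname(W))) stopf("W must be symmetric")
  if (any(diag(W) != 0)) stopf("W must have a zero diagonal")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  Q <- rho * (diag(rowSums(W), nrow(W)) - W) + (1 - rho) * diag(nrow(W))
  if (sparse) methods::as(methods::as(Matrix::Matrix(Q), "generalMatrix"), "CsparseMatrix") else Q
}

## Eigenvalues of the graph Laplacian diag(W1) - W; Q(rho) shares its
## eigenvectors, so log det Q = sum(log(rho * mu + 1 - rho)) for any rho.
car_laplacian_eigen <- function(W) {
  W <- as.matrix(W)
  L <- diag(rowSums(W), nrow(W)) - W
  eigen(L, symmetric = TRUE, only.values = TRUE)$values
}

car_logdet <- function(lap_eigen, rho) sum(log(rho * lap_eigen + 1 - rho))

#' Draw a Leroux CAR field
#'
#' One seeded multivariate normal draw with covariance
#' `sigma2_phi * Q(W)^-1`; requires `rho < 1`.
#'
#' @param W binary symmetric adjacency matrix.
#' @param params a [leroux_params()].
#' @param seed optional integer seed.
#' @return Numeric vector of length `nrow(W)`.
#' @export
sample_car <- function(W, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$rho >= 1) stopf("rho must be < 1 to sample (Q singular at 1)")
  n <- nrow(as.matrix(W))
  if (params$sigma2_phi == 0) return(rep(0, n))
  Q <- leroux_precision(W, params$rho, sparse = FALSE)
  R <- chol(Q)
  ## x = R^-1 z has covariance Q^-1
  drop(backsolve(R, rnorm(n)) * sqrt(params$sigma2_phi))
}
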