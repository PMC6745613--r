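#' Model parameter bundle
#'
#' Regression coefficients plus the Matern and Leroux hyperparameter bundles,
#' i.e. `theta = (beta, sigma2_eta, kappa, sigma2_phi, rho)`.
#'
#' @param beta numeric vector of regression coefficients (intercept first).
#' @param matern a [matern_params()].
#' @param leroux a [leroux_params()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(beta, matern = matern_params(),
                         leroux = leroux_params()) {
  structure(list(beta = beta, matern = matern, leroux = leroux),
            class = "model_params")
}

#' Prior specification
#'
#' Hyperpriors used for fitting, following the internal parameterization of
#' latent Gaussian software: `beta ~ N(0, beta_var I)`; the CAR precision
#' `1/sigma2_phi ~ Gamma(shape, rate)`; `logit(rho) ~ N(mean, variance)` (the
#' 0.45 default is read as a VARIANCE; change `rho_logit_normal[2]` if a
#' precision was intended); `log(kappa) ~ N(log(8/m), 1)` with `m` the median
#' pairwise distance of the prediction grid; and `log(tau) ~ N(0, 1)` on the
#' SPDE scale parameter, a vague log-normal on `sigma2_eta` given `kappa`.
#'
#' @param m median pairwise grid distance (sets the `log kappa` prior mean).
#' @param beta_var prior variance of each regression coefficient.
#' @param car_prec_gamma `c(shape, rate)` of the Gamma prior on the CAR
#'   precision. The simulation study uses `c(5, 1)`.
#' @param rho_logit_normal `c(mean, variance)` of the normal prior on
#'   `logit(rho)`.
#' @param kappa_lognormal `c(mean, variance)` of the normal prior on
#'   `log(kappa)`; mean defaults to `log(8/m)`.
#' @param log_tau_normal `c(mean, variance)` of the normal prior on
#'   `log(tau)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(m, beta_var = 1e5, car_prec_gamma = c(1, 0.01),
                       rho_logit_normal = c(0, 0.45),
                       kappa_lognormal = c(log(8 / m), 1),
                       log_tau_normal = c(0, 1)) {
  if (beta_var <= 0 || any(car_prec_gamma <= 0) ||
      rho_logit_normal[2] <= 0 || kappa_lognormal[2] <= 0 ||
      log_tau_normal[2] <= 0)
    stopf("prior hyperparameters must be positive where required")
  structure(list(m = m, beta_var = beta_var, car_prec_gamma = car_prec_gamma,
                 rho_logit_normal = rho_logit_normal,
                 kappa_lognormal = kappa_lognormal,
                 log_tau_normal = log_tau_normal),
            class = "prior_spec")
}

#' Area-level linear predictor
#'
#' `logit(p_i) = x_tilde_i' beta + eta_bar_i + phi_i`, where `eta_bar` is the
#' area-averaged Gaussian process and `phi` the CAR field.
#'
#' @param params a [model_params()].
#' @param cov a [covariate_stack()].
#' @param eta_area nA-vector of area-averaged GP values.
#' @param phi nA-vector of CAR values.
#' @return nA-vector of logits.
#' @export
linear_predictor_area <- function(params, cov, eta_area, phi) {
  nA <- nrow(cov$X_area)
  if (length(eta_area) != nA || length(phi) != nA ||
      length(params$beta) != ncol(cov$X_area))
    stopf("dimension mismatch in area-level predictor")
  drop(cov$X_area %*% params$beta) + eta_area + phi
}

#' Grid-level linear predictor
#'
#' `logit(p_i) = x_i' beta + eta(s_i) + phi_{A_i}`; cells outside the
#' partition (membership NA) take `phi = 0` and should be flagged downstream.
#'
#' @param params a [model_params()].
#' @param cov a [covariate_stack()].
#' @param eta np-vector of GP values at grid points.
#' @param phi nA-vector of CAR values.
#' @param membership integer area index per grid cell (NA outside).
#' @return np-vector of logits.
#' @export
linear_predictor_grid <- function(params, cov, eta, phi, membership) {
  np <- nrow(cov$X_grid)
  if (length(eta) != np || length(membership) != np ||
      length(params$beta) != ncol(cov$X_grid))
    stopf("dimension mismatch in grid-level predictor")
  phi_cell <- ifelse(is.na(membership), 0, phi[membership])
  drop(cov$X_grid %*% params$beta) + eta + phi_cell
}

#' Binomial log likelihood
#'
#' Sum of `log C(N,Y) + Y log p + (N - Y) log(1 - p)` over observed areas;
#' probabilities are clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param Y,N success counts and sample sizes.
#' @param p success probabilities.
#' @param observed logical mask; masked entries contribute zero.
#' @return Scalar log likelihood.
#' @export
binomial_loglik <- function(Y, N, p, observed = NULL) {
  observed <- observed %||% rep(TRUE, length(Y))
  Y <- Y[observed]; N <- N[observed]; p <- clip_prob(p[observed])
  if (any(Y > N)) stopf("Y must not exceed N")
  sum(lchoose(N, Y) + Y * log(p) + (N - Y) * log1p(-p))
}

#' Log prior density of the model parameters
#'
#' Joint prior density of `(beta, sigma2_eta & kappa, sigma2_phi, rho)` in
#' their natural parameterization, i.e. including the Jacobians of the
#' internal transforms: Gamma on the CAR precision, normal on `logit(rho)`,
#' normal on `log(kappa)` and normal on `log(tau)` (the SPDE scale implied by
#' `kappa` and `sigma2_eta`). Out-of-support parameters return `-Inf`.
#'
#' @param params a [model_params()].
#' @param priors a [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(params, priors) {
  b <- params$beta
  s2e <- params$matern$sigma2_eta
  kap <- params$matern$kappa
  s2p <- params$leroux$sigma2_phi
  rho <- params$leroux$rho
  if (s2e <= 0 || kap <= 0 || s2p <= 0 || rho <= 0 || rho >= 1) return(-Inf)
  lp <- sum(dnorm(b, 0, sqrt(priors$beta_var), log = TRUE))
  ## precision ~ Gamma(a, b); density in sigma2_phi with Jacobian prec^2
  prec <- 1 / s2p
  lp <- lp + dgamma(prec, priors$car_prec_gamma[1],
                    rate = priors$car_prec_gamma[2], log = TRUE) +
    2 * log(prec)
  ## logit(rho) ~ N(mean, var); density in rho with Jacobian 1/(rho(1-rho))
  lp <- lp + dnorm(logit(rho), priors$rho_logit_normal[1],
                   sqrt(priors$rho_logit_normal[2]), log = TRUE) -
    log(rho) - log1p(-rho)
  ## log(kappa) ~ N(log(8/m), var); density in kappa
  lp <- lp + dnorm(log(kap), priors$kappa_lognormal[1],
                   sqrt(priors$kappa_lognormal[2]), log = TRUE) - log(kap)
  ## log(tau) ~ N(0, var); tau = tau(kappa, sigma2_eta); density in sigma2_eta
  ## given kappa: |d log tau / d sigma2_eta| = 1/(2 sigma2_eta)
  lp <- lp + dnorm(log(spde_tau(kap, s2e)), priors$log_tau_normal[1],
                   sqrt(priors$log_tau_normal[2]), log = TRUE) -
    log(2 * s2e)
  lp
}

## prior density on the internal transformed scale
## theta_t = (log_tau, log_kappa, log_prec_phi, logit_rho)
log_prior_internal <- function(theta_t, priors) {
  dnorm(theta_t[1], priors$log_tau_normal[1],
        sqrt(priors$log_tau_normal[2]), log = TRUE) +
    dnorm(theta_t[2], priors$kappa_lognormal[1],
          sqrt(priors$kappa_lognormal[2]), log = TRUE) +
    ## prec ~ Gamma(a, b) => density of log prec adds Jacobian prec
    dgamma(exp(theta_t[3]), priors$car_prec_gamma[1],
           rate = priors$car_prec_gamma[2], log = TRUE) + theta_t[3] +
    dnorm(theta_t[4], priors$rho_logit_normal[1],
          sqrt(priors$rho_logit_normal[2]), log = TRUE)
}

theta_internal_to_natural <- function(theta_t) {
  tau <- exp(theta_t[1]); kap <- exp(theta_t[2])
  list(tau = tau, kappa = kap, sigma2_eta = spde_sigma2(kap, tau),
       sigma2_phi = exp(-theta_t[3]), rho = invlogit(theta_t[4]))
}

theta_natural_to_internal <- function(sigma2_eta, kappa, sigma2_phi, rho) {
  c(log_tau = log(spde_tau(kappa, sigma2_eta)), log_kappa = log(kappa),
    log_prec_phi = -log(sigma2_phi), logit_rho = logit(rho))
}

#' Joint log posterior of parameters and latent fields
#'
#' Evaluates, up to an additive constant, the augmented-data joint density:
#' binomial log likelihood of the observed areal counts at the area-level
#' predictor, plus the GMRF log density of the SPDE weights, the CAR log
#' density of `phi`, and [log_prior()].
#'
#' @param params a [model_params()].
#' @param eta_weights G-vector of SPDE basis weights.
#' @param phi nA-vector of CAR values.
#' @param data an [areal_counts()].
#' @param cov a [covariate_stack()].
#' @param mesh an `spde_mesh` (provides `A_areas` and the FEM matrices).
#' @param W adjacency matrix of the partition.
#' @param priors a [prior_spec()].
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(params, eta_weights, phi, data, cov, mesh, W,
                          priors) {
  eta_area <- as.numeric(mesh$A_areas %*% eta_weights)
  lin <- linear_predictor_area(params, cov, eta_area, phi)
  ll <- binomial_loglik(data$Y, data$N, invlogit(lin), data$observed)
  Qe <- spde_precision(mesh, params$matern)
  lgp <- 0.5 * logdet_sparse(Qe) -
    0.5 * quad_form(eta_weights, Qe)
  Qp <- leroux_precision(W, params$leroux$rho) / params$leroux$sigma2_phi
  ld_p <- car_logdet(car_laplacian_eigen(W), params$leroux$rho) -
    nrow(W) * log(params$leroux$sigma2_phi)
  lcar <- 0.5 * ld_p - 0.5 * quad_form(phi, Qp)
  ll + lgp + lcar + log_prior(params, priors)
}

logdet_sparse <- function(Q) {
  ch <- Matrix::Cholesky(methods::as(Q, "CsparseMatrix"), LDL = FALSE,
                         perm = TRUE)
  as.numeric(2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

#' Cluster-to-grid joint log posterior
#'
#' The point-data variant: cluster counts observed at known coordinates, no
#' areal CAR field, `logit(p_i) = x_i' beta + eta(s_i)` at both the clusters
#' and the grid. Used when geolocated cluster-level data are available.
#'
#' @param beta regression coefficients.
#' @param matern a [matern_params()].
#' @param eta_weights G-vector of SPDE basis weights.
#' @param cluster_data list with `Y`, `N`, `coords` (nc x 2, inside the mesh),
#'   and `X` (nc x k design matrix).
#' @param mesh an `spde_mesh`.
#' @param priors a [prior_spec()].
#' @return Scalar log posterior (unnormalized).
#' @export
cluster_model_logposterior <- function(beta, matern, eta_weights,
                                       cluster_data, mesh, priors) {
  A_c <- mesh_point_projector(mesh, cluster_data$coords)
  lin <- drop(cluster_data$X %*% beta) + as.numeric(A_c %*% eta_weights)
  ll <- binomial_loglik(cluster_data$Y, cluster_data$N, invlogit(lin))
  Qe <- spde_precision(mesh, matern)
  lgp <- 0.5 * logdet_sparse(Qe) -
    0.5 * quad_form(eta_weights, Qe)
  lp <- sum(dnorm(beta, 0, sqrt(priors$beta_var), log = TRUE)) +
    dnorm(log(spde_tau(matern$kappa, matern$sigma2_eta)),
          priors$log_tau_normal[1], sqrt(priors$log_tau_normal[2]),
          log = TRUE) +
    dnorm(log(matern$kappa), priors$kappa_lognormal[1],
          sqrt(priors$kappa_lognormal[2]), log = TRUE)
  ll + lgp + lp
}
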