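#' Fit the area-to-grid disaggregation model
#'
#' Computes the posterior of the hyperparameters and latent fields of the
#' joint binomial disaggregation model, with two interchangeable engines:
#'
#' * `"laplace"`: inner Newton iterations on the latent Gaussian field
#'   (sparse solves) nested inside a quasi-Newton/simplex search over the
#'   transformed hyperparameters, maximizing the Laplace-approximated
#'   marginal posterior; hyperparameter uncertainty from a finite-difference
#'   Hessian at the mode. Posterior draws are then generated by sampling
#'   hyperparameters from their Gaussian approximation and the latent field
#'   from its conditional Gaussian approximation.
#' * `"mcmc"`: a one-block Metropolis-Hastings sampler: a random-walk
#'   proposal on the transformed hyperparameters combined with a latent-field
#'   proposal drawn from the conditional Gaussian approximation at the
#'   proposed hyperparameters, accepted or rejected jointly. Reports split
#'   R-hat and effective sample sizes.
#'
#' Hyperparameters are handled on transformed scales
#' `(log tau, log kappa, log CAR-precision, logit rho)` matching the prior
#' parameterization. Areas with `observed = FALSE` contribute no likelihood
#' but receive full posterior predictors.
#'
#' @param data an [areal_counts()].
#' @param cov a [covariate_stack()].
#' @param partition an [area_partition()].
#' @param grid a [grid_domain()] (prediction support; also sets the median
#'   distance `m` of the kappa prior).
#' @param priors a [prior_spec()]; defaults to `prior_spec(m)` with `m` the
#'   median pairwise grid distance.
#' @param engine `"laplace"` or `"mcmc"`.
#' @param seed optional integer seed.
#' @param controls list of engine controls; see Details. Recognised keys:
#'   `mesh`, `max_edge`, `offset`, `membership`, `n_theta`, `n_latent`,
#'   `outer_maxit`, `outer_reltol`, `inner_tol`, `fix_theta`, `chains`,
#'   `warmup`, `iter`, `proposal_scale`, `verbose`.
#' @return An object of class `disagg_fit` with elements `engine`,
#'   `theta_summary` (parameter, mean, sd, q025, q975), `beta_summary`,
#'   `z_samples` (latent draws: beta, SPDE weights, phi), `theta_mode`,
#'   `theta_cov`, `diagnostics`, and the model context needed by
#'   [predict.disagg_fit()].
#' @export
disagg_fit <- function(data, cov, partition, grid, priors = NULL,
                       engine = c("laplace", "mcmc"), seed = NULL,
                       controls = list()) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  ctx <- build_fit_context(data, cov, partition, grid, priors, controls)
  fit <- if (engine == "laplace") fit_laplace(ctx, controls)
         else fit_mcmc(ctx, controls)
  fit$engine <- engine
  fit$seed <- seed
  class(fit) <- "disagg_fit"
  fit
}

#' @export
print.disagg_fit <- function(x, ...) {
  cat(sprintf("<disagg_fit> engine=%s, latent dim=%d, %d posterior draws\n",
              x$engine, nrow(x$z_samples), ncol(x$z_samples)))
  print(x$theta_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

build_fit_context <- function(data, cov, partition, grid, priors, controls) {
  membership <- controls$membership %||% grid$membership %||%
    assign_membership(grid, partition)
  m <- median_pairwise_distance(grid)
  priors <- priors %||% prior_spec(m = m)
  mesh <- controls$mesh %||%
    build_mesh(partition, max_edge = controls$max_edge,
               offset = controls$offset, points = grid)
  if (is.null(mesh$A_points)) mesh$A_points <- mesh_point_projector(mesh, grid)
  k <- ncol(cov$X_grid)
  G <- nrow(mesh$vertices)
  nA <- n_areas(partition)
  obs <- which(data$observed)
  ## observation matrix: rows = observed areas; columns = (beta, w, phi)
  M <- cbind(
    methods::as(Matrix::Matrix(cov$X_area[obs, , drop = FALSE]), "CsparseMatrix"),
    mesh$A_areas[obs, , drop = FALSE],
    methods::as(Matrix::Matrix(Matrix::Diagonal(nA)[obs, , drop = FALSE]), "CsparseMatrix")
  )
  list(
    data = data, cov = cov, partition = partition, grid = grid,
    membership = membership, mesh = mesh, priors = priors, m = m,
    k = k, G = G, nA = nA, obs = obs, M = M,
    Y = data$Y[obs], N = data$N[obs],
    W = partition$W, lap_eigen = car_laplacian_eigen(partition$W)
  )
}

## latent prior precision for internal theta; also returns its log det
latent_precision <- function(ctx, theta_t) {
  tau2 <- exp(2 * theta_t[1]); k2 <- exp(2 * theta_t[2])
  prec_phi <- exp(theta_t[3]); rho <- invlogit(theta_t[4])
  Qe <- tau2 * (k2 * k2 * ctx$mesh$fem$C + 2 * k2 * ctx$mesh$fem$G1 +
                  ctx$mesh$fem$G2)
  ld_e <- logdet_sparse(Qe)
  Qp <- prec_phi * leroux_precision(ctx$W, rho)
  ld_p <- ctx$nA * theta_t[3] + car_logdet(ctx$lap_eigen, rho)
  Qb <- Matrix::Diagonal(ctx$k, 1 / ctx$priors$beta_var)
  ld_b <- -ctx$k * log(ctx$priors$beta_var)
  Q <- Matrix::bdiag(Qb, Qe, Qp)
  list(Q = methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix"),
       logdet = ld_b + ld_e + ld_p)
}

## Newton maximization of loglik(Mz) - z' Q z / 2; returns mode, the
## posterior Cholesky, and useful byproducts. Warm start via z0.
inner_newton <- function(ctx, Q, z0 = NULL, tol = 1e-6, maxit = 50) {
  nz <- ctx$k + ctx$G + ctx$nA
  z <- z0 %||% numeric(nz)
  M <- ctx$M; Y <- ctx$Y; N <- ctx$N
  obj <- function(z, lin) {
    p <- clip_prob(invlogit(lin))
    sum(Y * log(p) + (N - Y) * log1p(-p)) -
      0.5 * quad_form(z, Q)
  }
  lin <- as.numeric(M %*% z)
  f <- obj(z, lin)
  ch <- NULL
  for (it in seq_len(maxit)) {
    p <- clip_prob(invlogit(lin))
    w <- pmax(N * p * (1 - p), 1e-10)
    H <- Matrix::forceSymmetric(Q + Matrix::crossprod(M, w * M))
    ch <- sparse_chol(H, ch)
    grad <- as.numeric(Matrix::crossprod(M, Y - N * p)) - as.numeric(Q %*% z)
    step <- as.numeric(Matrix::solve(ch, grad, system = "A"))
    ## line search with halving
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      lin_new <- as.numeric(M %*% z_new)
      f_new <- obj(z_new, lin_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { z_new <- z; lin_new <- lin; f_new <- f; break }
    }
    done <- abs(f_new - f) < tol * (1 + abs(f_new))
    z <- z_new; lin <- lin_new; f <- f_new
    if (done) break
  }
  ## refresh Hessian factor at the mode
  p <- clip_prob(invlogit(lin))
  w <- pmax(N * p * (1 - p), 1e-10)
  H <- Matrix::forceSymmetric(Q + Matrix::crossprod(M, w * M))
  ch <- sparse_chol(H, ch)
  list(z = z, lin = lin, chol = ch, loglik = binomial_part(Y, N, lin),
       quad = quad_form(z, Q), iterations = it,
       logdet_post = as.numeric(2 * Matrix::determinant(ch, sqrt = TRUE)$modulus))
}

binomial_part <- function(Y, N, lin) {
  p <- clip_prob(invlogit(lin))
  sum(lchoose(N, Y) + Y * log(p) + (N - Y) * log1p(-p))
}

sparse_chol <- function(H, previous = NULL) {
  if (!is.null(previous)) {
    out <- tryCatch(Matrix::update(previous, H), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
}

## Laplace-approximated log marginal posterior of internal theta
laplace_objective <- function(ctx, theta_t, state) {
  lp <- latent_precision(ctx, theta_t)
  nw <- inner_newton(ctx, lp$Q, z0 = state$z, tol = state$inner_tol)
  state$z <- nw$z
  val <- nw$loglik - 0.5 * nw$quad + 0.5 * lp$logdet -
    0.5 * nw$logdet_post + log_prior_internal(theta_t, ctx$priors)
  list(value = val, newton = nw, Qinfo = lp)
}

fit_laplace <- function(ctx, controls) {
  inner_tol <- controls$inner_tol %||% 1e-6
  state <- new.env()
  state$z <- NULL
  state$inner_tol <- inner_tol
  theta0 <- controls$theta_init %||%
    theta_natural_to_internal(sigma2_eta = 1, kappa = 8 / ctx$m,
                              sigma2_phi = 1, rho = 0.5)
  fixed <- !is.null(controls$fix_theta)
  if (fixed) {
    ft <- controls$fix_theta
    theta_hat <- theta_natural_to_internal(ft$sigma2_eta, ft$kappa,
                                           ft$sigma2_phi, ft$rho)
    opt_val <- laplace_objective(ctx, theta_hat, state)$value
    conv <- 0L
  } else {
    opt <- optim(
      theta0,
      function(th) -laplace_objective(ctx, th, state)$value,
      method = "Nelder-Mead",
      control = list(maxit = controls$outer_maxit %||% 500,
                     reltol = controls$outer_reltol %||% 1e-8)
    )
    theta_hat <- opt$par
    opt_val <- -opt$value
    conv <- opt$convergence
  }
  ## curvature of the marginal posterior at the mode
  if (fixed) {
    theta_cov <- matrix(0, 4, 4)
  } else {
    Hmat <- fd_hessian(function(th) laplace_objective(ctx, th, state)$value,
                       theta_hat, h = controls$fd_step %||% 0.05)
    theta_cov <- safe_inverse(-Hmat)
  }
  ## posterior draws: hyperparameters from the Gaussian approximation,
  ## latent field from its conditional Gaussian at each draw
  n_theta <- controls$n_theta %||% 8
  n_latent <- controls$n_latent %||% 125
  if (fixed) n_theta <- 0
  Lth <- tryCatch(chol(theta_cov), error = function(e) NULL)
  theta_draws <- matrix(rep(theta_hat, n_theta + 1), ncol = 4, byrow = TRUE)
  if (n_theta > 0 && !is.null(Lth)) {
    theta_draws[-1, ] <- theta_draws[-1, , drop = FALSE] +
      matrix(rnorm(4 * n_theta), n_theta, 4) %*% Lth
  }
  nz <- ctx$k + ctx$G + ctx$nA
  zs <- matrix(0, nz, (n_theta + 1) * n_latent)
  col0 <- 0
  for (tdx in seq_len(nrow(theta_draws))) {
    lo <- laplace_objective(ctx, theta_draws[tdx, ], state)
    nw <- lo$newton
    eps <- matrix(rnorm(nz * n_latent), nz, n_latent)
    ## N(mode, H^-1): solve L' u = eps, then undo the fill-reducing permutation
    u <- Matrix::solve(nw$chol, eps, system = "Lt")
    u <- as.matrix(Matrix::solve(nw$chol, u, system = "Pt"))
    zs[, col0 + seq_len(n_latent)] <- nw$z + u
    col0 <- col0 + n_latent
  }
  mode_fit <- laplace_objective(ctx, theta_hat, state)
  summaries <- summarize_fit(ctx, theta_hat, theta_cov, theta_draws, zs)
  c(list(
    z_samples = zs, theta_mode = theta_hat, theta_cov = theta_cov,
    theta_draws = theta_draws, ctx = ctx,
    latent_mode = mode_fit$newton$z,
    log_marginal = opt_val,
    diagnostics = list(convergence = conv,
                       newton_iterations = mode_fit$newton$iterations)
  ), summaries)
}

fd_hessian <- function(f, x, h = 0.05) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  fp <- fm <- numeric(n)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h)
    fp[i] <- f(x + ei); fm[i] <- f(x - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ei <- replace(numeric(n), i, h); ej <- replace(numeric(n), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] +
           f(x - ei - ej)) / (2 * h^2)
    }
  }
  H
}

safe_inverse <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  ok <- !is.null(out) && all(is.finite(out)) && all(diag(out) > 0)
  if (ok) {
    ev <- eigen(out, symmetric = TRUE)
    if (min(ev$values) <= 0) ok <- FALSE
  }
  if (!ok) {
    warning("hyperparameter Hessian not positive definite; ",
            "using a diagonal fallback for theta uncertainty")
    d <- abs(diag(A))
    out <- diag(ifelse(d > 1e-12, 1 / d, 1e4), nrow(A))
  }
  (out + t(out)) / 2
}

summarize_fit <- function(ctx, theta_hat, theta_cov, theta_draws, zs,
                          n_theta_mc = 4000) {
  ## hyperparameters on natural scales via Monte Carlo through the transform
  Lth <- tryCatch(chol(theta_cov), error = function(e) NULL)
  if (is.null(Lth) || all(theta_cov == 0)) {
    tmc <- matrix(rep(theta_hat, 2), 2, 4, byrow = TRUE)
  } else {
    tmc <- matrix(rep(theta_hat, n_theta_mc), n_theta_mc, 4, byrow = TRUE) +
      matrix(rnorm(4 * n_theta_mc), n_theta_mc, 4) %*% Lth
  }
  nat <- data.frame(
    sigma2_eta = spde_sigma2(exp(tmc[, 2]), exp(tmc[, 1])),
    kappa = exp(tmc[, 2]),
    range = kappa_to_range(exp(tmc[, 2])),
    sigma2_phi = exp(-tmc[, 3]),
    rho = invlogit(tmc[, 4])
  )
  beta_idx <- seq_len(ctx$k)
  bd <- as.data.frame(t(zs[beta_idx, , drop = FALSE]))
  names(bd) <- paste0("beta_", ctx$cov$names)
  all_draws <- cbind(bd,
                     nat[rep(seq_len(nrow(nat)), length.out = nrow(bd)), ])
  theta_summary <- do.call(rbind, lapply(names(all_draws), function(nm) {
    v <- all_draws[[nm]]
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               q025 = unname(quantile(v, 0.025)),
               q975 = unname(quantile(v, 0.975)))
  }))
  beta_summary <- theta_summary[seq_len(ctx$k), ]
  list(theta_summary = theta_summary, beta_summary = beta_summary)
}

## ---- MCMC engine -----------------------------------------------------------

fit_mcmc <- function(ctx, controls) {
  chains <- controls$chains %||% 4
  warmup <- controls$warmup %||% 1000
  iter <- controls$iter %||% 1000
  inner_tol <- controls$inner_tol %||% 1e-6
  ## initial Laplace pass provides the proposal covariance and starting points
  lap <- fit_laplace(ctx, modifyList(as.list(controls),
                                     list(n_theta = 0, n_latent = 2)))
  theta_hat <- lap$theta_mode
  Sprop <- lap$theta_cov
  if (all(Sprop == 0)) Sprop <- diag(1e-4, 4)
  Lprop <- chol(Sprop + diag(1e-8, 4))
  nz <- ctx$k + ctx$G + ctx$nA
  state <- new.env(); state$inner_tol <- inner_tol
  joint_logpost <- function(theta_t, z, Qinfo) {
    binomial_part(ctx$Y, ctx$N, as.numeric(ctx$M %*% z)) -
      0.5 * quad_form(z, Qinfo$Q) + 0.5 * Qinfo$logdet +
      log_prior_internal(theta_t, ctx$priors)
  }
  kept_theta <- vector("list", chains)
  kept_z <- vector("list", chains)
  accept_rate <- numeric(chains)
  for (chn in seq_len(chains)) {
    scale <- 0.8
    theta <- theta_hat + drop(rnorm(4) %*% Lprop) * 0.5
    lpQ <- latent_precision(ctx, theta)
    state$z <- lap$latent_mode
    nw <- inner_newton(ctx, lpQ$Q, z0 = state$z, tol = inner_tol)
    ## draw initial z from the approximation at theta
    z <- draw_from_newton(nw, nz)
    lq_z <- gauss_dens_at(ctx, lpQ, nw, z)
    lj <- joint_logpost(theta, z, lpQ)
    th_out <- matrix(NA_real_, iter, 4)
    z_out <- matrix(NA_real_, nz, iter)
    n_acc <- 0; n_try <- 0
    for (t in seq_len(warmup + iter)) {
      theta_star <- theta + drop(rnorm(4) %*% Lprop) * scale
      lpQ_star <- latent_precision(ctx, theta_star)
      nw_star <- inner_newton(ctx, lpQ_star$Q, z0 = z, tol = inner_tol)
      z_star <- draw_from_newton(nw_star, nz)
      lq_star <- gauss_dens_at(ctx, lpQ_star, nw_star, z_star)
      lj_star <- joint_logpost(theta_star, z_star, lpQ_star)
      log_alpha <- (lj_star - lj) + (lq_z - lq_star)
      n_try <- n_try + 1
      if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
        theta <- theta_star; z <- z_star; lj <- lj_star; lq_z <- lq_star
        lpQ <- lpQ_star; nw <- nw_star
        n_acc <- n_acc + 1
      }
      if (t <= warmup) {
        gam <- min(0.25, 2 / sqrt(t))
        acc <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
        scale <- scale * exp(gam * (acc - 0.25))
      } else {
        th_out[t - warmup, ] <- theta
        z_out[, t - warmup] <- z
      }
    }
    kept_theta[[chn]] <- th_out
    kept_z[[chn]] <- z_out
    accept_rate[chn] <- n_acc / n_try
  }
  theta_all <- do.call(rbind, kept_theta)
  zs <- do.call(cbind, kept_z)
  rhat <- apply_split_rhat(kept_theta)
  ess <- vapply(seq_len(4), function(j)
    ess_from_chains(lapply(kept_theta, function(m) m[, j])), numeric(1))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning(sprintf("split R-hat above 1.05 for %d hyperparameter(s); ",
                    sum(rhat > 1.05, na.rm = TRUE)),
            "consider more iterations")
  summaries <- summarize_mcmc(ctx, theta_all, zs)
  c(list(
    z_samples = zs, theta_mode = lap$theta_mode, theta_cov = lap$theta_cov,
    theta_draws = theta_all, ctx = ctx, latent_mode = lap$latent_mode,
    log_marginal = lap$log_marginal,
    diagnostics = list(accept_rate = accept_rate, split_rhat = rhat,
                       ess = ess, chains = chains, iter = iter,
                       warmup = warmup)
  ), summaries)
}

draw_from_newton <- function(nw, nz) {
  u <- Matrix::solve(nw$chol, rnorm(nz), system = "Lt")
  nw$z + drop(as.matrix(Matrix::solve(nw$chol, u, system = "Pt")))
}

## exact Gaussian log density of the Newton approximation N(z*, H^-1)
gauss_dens_at <- function(ctx, lpQ, nw, z) {
  d <- z - nw$z
  p <- clip_prob(invlogit(nw$lin))
  w <- pmax(ctx$N * p * (1 - p), 1e-10)
  quad <- quad_form(d, lpQ$Q) +
    sum((as.numeric(ctx$M %*% d))^2 * w)
  0.5 * nw$logdet_post - 0.5 * quad
}

summarize_mcmc <- function(ctx, theta_all, zs) {
  nat <- data.frame(
    sigma2_eta = spde_sigma2(exp(theta_all[, 2]), exp(theta_all[, 1])),
    kappa = exp(theta_all[, 2]),
    range = kappa_to_range(exp(theta_all[, 2])),
    sigma2_phi = exp(-theta_all[, 3]),
    rho = invlogit(theta_all[, 4])
  )
  bd <- t(zs[seq_len(ctx$k), , drop = FALSE])
  colnames(bd) <- paste0("beta_", ctx$cov$names)
  all_draws <- cbind(as.data.frame(bd), nat)
  theta_summary <- do.call(rbind, lapply(names(all_draws), function(nm) {
    v <- all_draws[[nm]]
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               q025 = unname(quantile(v, 0.025)),
               q975 = unname(quantile(v, 0.975)))
  }))
  list(theta_summary = theta_summary,
       beta_summary = theta_summary[seq_len(ctx$k), ])
}

apply_split_rhat <- function(chain_list) {
  vapply(seq_len(ncol(chain_list[[1]])), function(j) {
    split_rhat(lapply(chain_list, function(m) m[, j]))
  }, numeric(1))
}

## split-R-hat (Gelman et al.): halve each chain, compare within/between
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, var, numeric(1))
  n <- length(halves[[1]])
  W <- mean(vrs)
  B <- n * var(mns)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## effective sample size via Geyer's initial monotone positive sequence
ess_from_chains <- function(chains) {
  n <- length(chains[[1]])
  m <- length(chains)
  rho_sum <- 0
  for (x in chains) {
    a <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pair <- a[seq(1, length(a) - 1, by = 2)] + a[seq(2, length(a), by = 2)]
    pos <- which(pair <= 0)
    keep <- if (length(pos)) 2 * (pos[1] - 1) else length(a)
    rho_sum <- rho_sum + sum(a[seq_len(keep)])
  }
  rho_bar <- rho_sum / m
  m * n / (1 + 2 * max(rho_bar, 0))
}
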