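test_that("linear predictors reproduce hand-computed logits", {
  mem <- c(1, 1, 2, 2)
  X <- cbind(1, c(0.5, -0.5, 2, 0))
  cov <- covariate_stack(X, mem, 2)
  prm0 <- model_params(beta = c(0, 0))
  ## all-zero fields and coefficients give p = 0.5 at both supports
  expect_equal(plogis(linear_predictor_area(prm0, cov, rep(0, 2), rep(0, 2))),
               rep(0.5, 2))
  expect_equal(plogis(linear_predictor_grid(prm0, cov, rep(0, 4), rep(0, 2),
                                            mem)),
               rep(0.5, 4))
  ## intercept-only hand sum: 0.2 + 0.1 - 0.3 = 0
  cov1 <- covariate_stack(matrix(1, 2, 1), c(1, 2), 2)
  lp <- linear_predictor_area(model_params(beta = 0.2), cov1,
                              c(0.1, 0.1), c(-0.3, -0.3))
  expect_equal(plogis(lp), c(0.5, 0.5))
  ## grid toy: k = 1 (intercept), eta and phi shift two cells of one area
  lpg <- linear_predictor_grid(model_params(beta = 1),
                               covariate_stack(matrix(1, 2, 1), c(1, 1), 1),
                               c(0.5, -0.5), 2, c(1, 1))
  expect_equal(lpg, c(3.5, 2.5))
  ## cells outside the partition take phi = 0
  lp_out <- linear_predictor_grid(model_params(beta = 1),
                                  covariate_stack(matrix(1, 2, 1),
                                                  c(1, 1), 1),
                                  c(0, 0), 5, c(1, NA))
  expect_equal(lp_out, c(6, 1))
  expect_error(linear_predictor_area(prm0, cov, rep(0, 3), rep(0, 2)),
               "dimension")
})

test_that("grid and area predictors agree when fields are area-constant", {
  p <- build_unit_square_partition(2)
  g <- build_grid(8, 8)
  mem <- assign_membership(g, p)
  ## covariates constant within each area
  xa <- c(0.3, -1, 2, 0.5)
  X <- cbind(1, xa[mem])
  cov <- covariate_stack(X, mem, 4)
  prm <- model_params(beta = c(0.2, -0.4))
  eta_area <- c(1, -1, 0.5, 0)
  phi <- c(0.1, 0.2, -0.3, 0)
  lp_area <- linear_predictor_area(prm, cov, eta_area, phi)
  lp_grid <- linear_predictor_grid(prm, cov, eta_area[mem], phi, mem)
  expect_equal(lp_grid, lp_area[mem])
})

test_that("binomial log likelihood matches dbinom and handles masks", {
  expect_equal(binomial_loglik(2, 2, 1 - 1e-15), 0)
  expect_equal(binomial_loglik(1, 2, 0.5), log(0.5))
  ## oracle: sum of dbinom log densities
  set.seed(2)
  N <- c(10, 25, 40); Y <- c(3, 20, 11); p <- c(0.2, 0.7, 0.4)
  expect_equal(binomial_loglik(Y, N, p), sum(dbinom(Y, N, p, log = TRUE)))
  ## masked areas contribute nothing
  expect_equal(binomial_loglik(c(Y, 99), c(N, NA), c(p, 0.5),
                               observed = c(TRUE, TRUE, TRUE, FALSE)),
               sum(dbinom(Y, N, p, log = TRUE)))
  expect_error(binomial_loglik(3, 2, 0.5), "exceed")
})

test_that("log prior reproduces each stated prior component", {
  pr <- prior_spec(m = 0.5)
  prm <- model_params(beta = c(0, 0, 0),
                      matern = matern_params(1, 8 / 0.5),
                      leroux = leroux_params(1, 0.5))
  lp <- log_prior(prm, pr)
  ## independent recomputation of every term
  expected <- 3 * dnorm(0, 0, sqrt(1e5), log = TRUE) +
    (dgamma(1, 1, rate = 0.01, log = TRUE) + 2 * log(1)) +
    (dnorm(0, 0, sqrt(0.45), log = TRUE) - log(0.5) - log(0.5)) +
    (dnorm(log(16), log(16), 1, log = TRUE) - log(16)) +
    (dnorm(log(1 / (16 * sqrt(4 * pi))), 0, 1, log = TRUE) - log(2))
  expect_equal(lp, expected)
  ## out-of-support parameters
  prm_bad <- model_params(beta = 0, matern = matern_params(1, 2),
                          leroux = leroux_params(1, 0.5))
  prm_bad$leroux$rho <- 1
  expect_equal(log_prior(prm_bad, pr), -Inf)
})

test_that("joint log posterior is additive and label-permutation invariant", {
  p <- build_unit_square_partition(2)
  g <- build_grid(8, 8)
  mem <- assign_membership(g, p)
  set.seed(31)
  X <- cbind(1, rnorm(64))
  cov <- covariate_stack(X, mem, 4)
  mesh <- build_mesh(p, max_edge = 0.2)
  G <- nrow(mesh$vertices)
  w <- rnorm(G, sd = 0.3)
  phi <- rnorm(4, sd = 0.5)
  counts <- areal_counts(c(30, 55, 20, 41), c(60, 80, 50, 70))
  prm <- model_params(beta = c(0.1, 0.3),
                      matern = matern_params(1, range_to_kappa(0.5)),
                      leroux = leroux_params(0.8, 0.4))
  pr <- prior_spec(m = 0.5)
  lp <- log_posterior(prm, w, phi, counts, cov, mesh, p$W, pr)
  expect_true(is.finite(lp))
  ## additivity: recompute the four components independently
  eta_area <- as.numeric(mesh$A_areas %*% w)
  ll <- binomial_loglik(counts$Y, counts$N,
                        plogis(linear_predictor_area(prm, cov, eta_area, phi)))
  Qe <- as.matrix(spde_precision(mesh, prm$matern))
  lgp <- 0.5 * determinant(Qe)$modulus[1] - 0.5 * drop(t(w) %*% Qe %*% w)
  Qp <- as.matrix(leroux_precision(p$W, 0.4)) / 0.8
  lcar <- 0.5 * determinant(Qp)$modulus[1] - 0.5 * drop(t(phi) %*% Qp %*% phi)
  expect_equal(lp, ll + lgp + lcar + log_prior(prm, pr) +
                 ## CAR normal constant differences cancel in both routes
                 0, tolerance = 1e-8)
  ## permuting area labels consistently leaves the value unchanged
  perm <- c(3, 1, 4, 2)
  p_perm <- p
  p_perm$polygons <- p$polygons[perm]
  p_perm$W <- p$W[perm, perm]
  p_perm$area_ids <- p$area_ids[perm]
  mem_perm <- match(mem, perm)
  cov_perm <- covariate_stack(X, mem_perm, 4)
  mesh_perm <- mesh
  mesh_perm$A_areas <- mesh$A_areas[perm, ]
  counts_perm <- areal_counts(counts$Y[perm], counts$N[perm])
  lp_perm <- log_posterior(prm, w, phi[perm], counts_perm, cov_perm,
                           mesh_perm, p_perm$W, pr)
  expect_equal(lp_perm, lp, tolerance = 1e-10)
  ## likelihood curvature: moving Y away from N p lowers the posterior
  counts_far <- areal_counts(c(5, 55, 20, 41), c(60, 80, 50, 70))
  expect_lt(log_posterior(prm, w, phi, counts_far, cov, mesh, p$W, pr), lp)
})

test_that("cluster-to-grid variant drops the CAR field but keeps structure", {
  p <- rect_partition(2, 1)
  mesh <- build_mesh(p, max_edge = 0.25)
  G <- nrow(mesh$vertices)
  pr <- prior_spec(m = 0.5)
  cl <- list(Y = c(4, 9), N = c(10, 12),
             coords = rbind(c(0.25, 0.5), c(0.75, 0.5)),
             X = cbind(1, c(0.2, -0.1)))
  mt <- matern_params(1, range_to_kappa(0.5))
  ## with a zero GP and beta = 0 the likelihood part is binomial at p = 0.5
  lp0 <- cluster_model_logposterior(c(0, 0), mt, rep(0, G), cl, mesh, pr)
  ll0 <- binomial_loglik(cl$Y, cl$N, rep(0.5, 2))
  Qe <- spde_precision(mesh, mt)
  const <- 0.5 * as.numeric(determinant(as.matrix(Qe))$modulus) +
    2 * dnorm(0, 0, sqrt(1e5), log = TRUE) +
    dnorm(log(1 / (mt$kappa * sqrt(4 * pi))), 0, 1, log = TRUE) +
    dnorm(log(mt$kappa), log(16), 1, log = TRUE)
  expect_equal(lp0, ll0 + const)
  ## GP weights enter through the point projector
  w <- rnorm(G, sd = 0.2)
  lp_w <- cluster_model_logposterior(c(0, 0), mt, w, cl, mesh, pr)
  A_c <- mesh_point_projector(mesh, cl$coords)
  ll_w <- binomial_loglik(cl$Y, cl$N, plogis(as.numeric(A_c %*% w)))
  expect_equal(lp_w - lp0,
               (ll_w - ll0) - 0.5 * as.numeric(t(w) %*% (Qe %*% w)),
               tolerance = 1e-10)
})
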