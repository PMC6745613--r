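test_that("intercept-only fit with vanishing spatial variance recovers the empirical proportion", {
  partition <- rect_partition(1, 1)
  grid <- build_grid(5, 5)
  mem <- assign_membership(grid, partition)
  grid$membership <- mem
  cov <- covariate_stack(matrix(1, 25, 1), mem, 1)
  counts <- areal_counts(140, 200)
  fit <- disagg_fit(counts, cov, partition, grid, seed = 4,
                    controls = list(max_edge = 0.4,
                                    fix_theta = list(sigma2_eta = 1e-6,
                                                     kappa = 4,
                                                     sigma2_phi = 1e-6,
                                                     rho = 0.5),
                                    n_latent = 600))
  pred <- predict(fit)
  expect_lt(max(abs(pred$mean - 0.7)), 0.03)
  expect_lt(abs(pred$area_estimates$mean[1] - 0.7), 0.03)
})

test_that("laplace fit returns a coherent posterior summary on a toy problem", {
  toy <- toy_problem()
  fit <- disagg_fit(toy$counts, toy$cov, toy$partition, toy$grid, seed = 21,
                    controls = quick_controls(toy))
  expect_s3_class(fit, "disagg_fit")
  ts <- fit$theta_summary
  expect_setequal(ts$parameter,
                  c("beta_intercept", "beta_x1", "sigma2_eta", "kappa",
                    "range", "sigma2_phi", "rho"))
  expect_true(all(is.finite(ts$mean) & is.finite(ts$sd)))
  expect_true(all(ts$q025 <= ts$mean & ts$mean <= ts$q975))
  pred <- predict(fit)
  expect_true(all(pred$lower95 <= pred$mean & pred$mean <= pred$upper95))
  expect_true(all(pred$mean >= 0 & pred$mean <= 1))
  expect_true(all(pred$sd >= 0))
  ## observed areas are fitted closely at the area level
  expect_gt(cor(pred$area_estimates$mean, toy$counts$Y / toy$counts$N), 0.9)
})

test_that("laplace objective and mode predictions are invariant to area relabelling", {
  toy <- toy_problem()
  fit1 <- disagg_fit(toy$counts, toy$cov, toy$partition, toy$grid, seed = 5,
                     controls = quick_controls(toy))
  perm <- c(2, 3, 1)
  partition2 <- toy$partition
  partition2$polygons <- toy$partition$polygons[perm]
  partition2$W <- toy$partition$W[perm, perm]
  partition2$area_ids <- toy$partition$area_ids[perm]
  mem2 <- match(toy$membership, perm)
  grid2 <- toy$grid; grid2$membership <- mem2
  cov2 <- covariate_stack(toy$cov$X_grid, mem2, 3)
  counts2 <- areal_counts(toy$counts$Y[perm], toy$counts$N[perm])
  fit2 <- disagg_fit(counts2, cov2, partition2, grid2, seed = 5,
                     controls = list(membership = mem2, n_theta = 4,
                                     n_latent = 100, max_edge = 0.12))
  expect_equal(fit2$log_marginal, fit1$log_marginal, tolerance = 1e-4)
  expect_equal(fit2$theta_mode, fit1$theta_mode, tolerance = 1e-2)
})

test_that("missing areas are estimated with full posterior predictors", {
  toy <- toy_problem()
  Y <- toy$counts$Y; N <- toy$counts$N
  Y[2] <- NA; N[2] <- NA
  counts <- areal_counts(Y, N)
  fit <- disagg_fit(counts, toy$cov, toy$partition, toy$grid, seed = 8,
                    controls = quick_controls(toy))
  pred <- predict(fit)
  ae <- pred$area_estimates
  expect_false(ae$observed[2])
  expect_true(is.finite(ae$mean[2]))
  expect_true(ae$lower[2] < ae$upper[2])
  ## the unobserved area is more uncertain than its observed neighbours
  expect_gt(ae$sd[2], min(ae$sd[-2]))
})

test_that("mcmc engine runs, adapts and emits the same summary schema", {
  toy <- toy_problem()
  fit <- disagg_fit(toy$counts, toy$cov, toy$partition, toy$grid,
                    engine = "mcmc", seed = 13,
                    controls = quick_controls(toy, list(chains = 2,
                                                        warmup = 100,
                                                        iter = 150)))
  expect_equal(fit$engine, "mcmc")
  expect_equal(ncol(fit$z_samples), 300)
  expect_length(fit$diagnostics$split_rhat, 4)
  expect_length(fit$diagnostics$ess, 4)
  expect_true(all(fit$diagnostics$accept_rate > 0.02))
  expect_setequal(fit$theta_summary$parameter,
                  c("beta_intercept", "beta_x1", "sigma2_eta", "kappa",
                    "range", "sigma2_phi", "rho"))
  pred <- predict(fit)
  expect_true(all(pred$lower95 <= pred$upper95))
})

test_that("credible intervals are equal-tailed, nested and Gaussian-consistent", {
  set.seed(77)
  x <- rnorm(40000)
  ci <- credible_interval(x, 0.95)
  expect_equal(unname(ci), c(-1.96, 1.96), tolerance = 0.03)
  ci50 <- credible_interval(x, 0.5)
  expect_lt(ci50[2] - ci50[1], ci[2] - ci[1])
  ## symmetric three-point draws at high level span the data range
  y <- rep(c(-1, 0, 1), 2000)
  ci99 <- credible_interval(y, 0.999)
  expect_equal(unname(ci99), c(-1, 1))
  ## Gaussian representation, optionally through the logit link
  cg <- credible_interval(list(mean = 0, sd = 1), 0.95)
  expect_equal(unname(cg[1, ]), c(-1.959964, 1.959964), tolerance = 1e-6)
  cl <- credible_interval(list(mean = 0, sd = 10), 0.95, logit_scale = TRUE)
  expect_true(all(cl >= 0 & cl <= 1))
  expect_error(credible_interval(numeric(0)), "empty")
  expect_error(credible_interval(x, 1.2), "level")
})
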