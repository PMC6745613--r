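# Shared builders for small, fast model problems used across test files.

# A well-identified 3-area toy: 3 vertical strips, 10 x 10 grid, intercept +
# one standard-normal covariate, moderate counts.
toy_problem <- function(seed = 101, N = 220) {
  set.seed(seed)
  partition <- rect_partition(3, 1)
  grid <- build_grid(10, 10)
  membership <- assign_membership(grid, partition)
  grid$membership <- membership
  X <- cbind(intercept = 1, x1 = rnorm(100))
  cov <- covariate_stack(X, membership, 3)
  eta <- sample_gp(grid, matern_params(0.5, range_to_kappa(0.5)))
  phi <- sample_car(partition$W, leroux_params(0.3, 0.5))
  p_area <- plogis(drop(cov$X_area %*% c(0.2, 0.4)) +
                     drop(block_average(eta, membership, 3)) + phi)
  Nv <- rep(N, 3)
  counts <- areal_counts(rbinom(3, Nv, p_area), Nv)
  mesh <- build_mesh(partition, max_edge = 0.12, points = grid)
  list(partition = partition, grid = grid, membership = membership,
       cov = cov, counts = counts, mesh = mesh, p_area = p_area)
}

quick_controls <- function(toy, extra = list()) {
  modifyList(list(mesh = toy$mesh, membership = toy$membership,
                  n_theta = 4, n_latent = 100), extra)
}

# reduced-size study setting used by structural tests
tiny_setting <- function() {
  sim_setting(r = 0.5, n_side = 3, grid_nx = 20, grid_ny = 20)
}
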