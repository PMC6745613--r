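test_that("range-scale conversion matches the printed pairs and inverts", {
  expect_equal(round(range_to_kappa(0.3), 1), 9.4)
  expect_equal(round(range_to_kappa(0.5), 1), 5.7)
  expect_equal(round(range_to_kappa(0.7), 1), 4.0)
  expect_equal(kappa_to_range(sqrt(8)), 1)
  for (r in c(0.05, 0.3, 2)) {
    expect_equal(kappa_to_range(range_to_kappa(r)), r)
  }
  expect_error(range_to_kappa(-1), "positive")
})

test_that("Matern covariance has the right variance, range behaviour and PSD", {
  mp <- matern_params(sigma2_eta = 2.5, kappa = range_to_kappa(0.3))
  D <- as.matrix(dist(cbind(runif(30), runif(30))))
  S <- matern_cov(D, mp)
  expect_equal(unname(diag(S)), rep(2.5, 30))
  expect_true(isSymmetric(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * 2.5)
  ## correlation at the practical range: direct Bessel evaluation
  ## sqrt(8) * K_1(sqrt(8)) for nu = 1
  rho_at_range <- sqrt(8) * besselK(sqrt(8), 1)
  expect_equal(matern_cov(matrix(c(0, 0.3, 0.3, 0), 2), mp)[1, 2] / 2.5,
               rho_at_range)
  expect_equal(rho_at_range, 0.139, tolerance = 0.01)
  ## decay to zero far beyond the range
  expect_lt(matern_cov(matrix(c(0, 50, 50, 0), 2),
                       matern_params(1, 1))[1, 2], 1e-10)
  expect_error(matern_cov(matrix(c(0, -1, -1, 0), 2), mp), "nonnegative")
})

test_that("GP draws reproduce the Matern moments", {
  pts <- rbind(c(0, 0), c(0.3, 0))  # distance = the practical range
  smp <- gp_sampler(pts, matern_params(1, range_to_kappa(0.3)))
  set.seed(5)
  draws <- smp(500)
  v <- var(draws[1, ])
  ## SE of a variance estimate: sqrt(2/(n-1))
  expect_lt(abs(v - 1), 3 * sqrt(2 / 499))
  r_emp <- cor(draws[1, ], draws[2, ])
  expect_lt(abs(r_emp - sqrt(8) * besselK(sqrt(8), 1)), 3 / sqrt(500))
  ## degenerate variance
  expect_equal(sample_gp(pts, matern_params(0, 1), seed = 1), c(0, 0))
  ## seeded reproducibility
  expect_identical(sample_gp(pts, matern_params(1, 3), seed = 9),
                   sample_gp(pts, matern_params(1, 3), seed = 9))
})

test_that("Leroux precision matches its closed form and limits", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(as.matrix(leroux_precision(W, 0)), diag(2), ignore_attr = TRUE)
  expect_equal(as.matrix(leroux_precision(W, 1)),
               diag(rowSums(W)) - W, ignore_attr = TRUE)
  expect_equal(as.matrix(leroux_precision(W, 0.6)),
               matrix(c(1, -0.6, -0.6, 1), 2), ignore_attr = TRUE)
  ## eigenvalues bounded below by 1 - rho
  W9 <- build_unit_square_partition(3)$W
  for (rho in c(0.1, 0.5, 0.9)) {
    ev <- eigen(as.matrix(leroux_precision(W9, rho)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), (1 - rho) - 1e-12)
  }
  expect_error(leroux_precision(matrix(c(0, 1, 0, 0), 2), 0.5), "symmetric")
  expect_error(leroux_precision(W, 1.2), "0, 1")
})

test_that("CAR draws match the implied covariance", {
  W <- build_unit_square_partition(2)$W
  prm <- leroux_params(sigma2_phi = 1.5, rho = 0.6)
  Sig_true <- 1.5 * solve(as.matrix(leroux_precision(W, 0.6)))
  set.seed(11)
  draws <- t(replicate(2000, sample_car(W, prm)))
  Sig_emp <- cov(draws)
  ## elementwise 4 SE tolerance for a covariance estimate
  se <- sqrt((outer(diag(Sig_true), diag(Sig_true)) + Sig_true^2) / 2000)
  expect_true(all(abs(Sig_emp - Sig_true) < 4 * se))
  ## independence and degenerate limits
  set.seed(3)
  iid <- t(replicate(1000, sample_car(W, leroux_params(2, 0))))
  expect_lt(max(abs(cov(iid) - 2 * diag(4))), 4 * sqrt((4 + 4) / 1000) * 2)
  expect_equal(sample_car(W, leroux_params(0, 0.5)), rep(0, 4))
  expect_error(sample_car(W, leroux_params(1, 1)), "singular")
})

test_that("mesh projectors interpolate points and average areas", {
  p <- build_unit_square_partition(2)
  mesh <- build_mesh(p, max_edge = 0.1)
  ## any point's barycentric weights sum to one
  pts <- cbind(runif(50), runif(50))
  A <- mesh_point_projector(mesh, pts)
  expect_equal(as.numeric(Matrix::rowSums(A)), rep(1, 50))
  ## a point at a vertex has an indicator row
  Av <- mesh_point_projector(mesh, mesh$vertices[c(10, 200), , drop = FALSE])
  expect_equal(as.numeric(Av[1, 10]), 1)
  expect_equal(as.numeric(Matrix::rowSums(Av != 0)), c(1, 1))
  ## area rows sum to one with equal 1/V_i weights
  expect_equal(as.numeric(Matrix::rowSums(mesh$A_areas)), rep(1, 4))
  aw <- mesh$A_areas[1, ]
  nz <- aw[aw != 0]
  expect_true(all(abs(nz - 1 / length(nz)) < 1e-12))
  ## interpolation is exact for linear functions of the coordinates
  f <- function(q) 2 * q[, 1] - 3 * q[, 2] + 1
  expect_equal(as.numeric(A %*% f(mesh$vertices)), f(pts))
})

test_that("an area containing exactly four vertices gets weights 0.25", {
  p1 <- rect_partition(1, 1)
  mesh <- build_mesh(p1, max_edge = 0.6, offset = 0.3)
  w <- as.numeric(mesh$A_areas[1, ])
  expect_equal(sum(w != 0), 4)
  expect_equal(w[w != 0], rep(0.25, 4))
})

test_that("SPDE precision reproduces the Matern field on a fine mesh", {
  p <- build_unit_square_partition(3)
  mesh <- build_mesh(p, max_edge = 0.04)
  v <- mesh$vertices
  prm <- matern_params(1, range_to_kappa(0.5))
  Q <- spde_precision(mesh, prm)
  expect_s4_class(Q, "dsCMatrix")
  ## implied marginal variance near sigma2_eta at vertices well inside
  sel <- which(abs(v[, 1] - 0.5) < 0.15 & abs(v[, 2] - 0.5) < 0.15)
  sel <- sel[seq(1, length(sel), length.out = 25)]
  E <- matrix(0, nrow(v), length(sel))
  E[cbind(sel, seq_along(sel))] <- 1
  S <- as.matrix(Matrix::solve(Q, E))[sel, ]
  expect_lt(max(abs(diag(S) - 1)), 0.1)
  ## implied correlation close to the closed form at those vertices
  Cs <- S / tcrossprod(sqrt(diag(S)))
  Ct <- matern_cov(as.matrix(dist(v[sel, ])), matern_params(1, prm$kappa))
  expect_lt(max(abs(Cs - Ct)), 0.05)
  ## larger kappa shrinks correlation at a fixed distance
  cor_at <- function(kap) {
    Qk <- spde_precision(mesh, matern_params(1, kap))
    Sk <- as.matrix(Matrix::solve(Qk, E[, 1:2]))[sel[1:2], ]
    Sk[1, 2] / sqrt(Sk[1, 1] * Sk[2, 2])
  }
  expect_gt(cor_at(3), cor_at(8))
  expect_error(spde_precision(mesh, matern_params(1, 3, nu = 2)), "nu = 1")
})

test_that("mesh files round-trip through the plain-text export", {
  p <- build_unit_square_partition(2)
  mesh <- build_mesh(p, max_edge = 0.3)
  stem <- file.path(tempdir(), "mesh_test")
  paths <- write_mesh(mesh, stem)
  vv <- as.matrix(read.table(paths[1], header = TRUE))
  expect_equal(unname(vv), unname(mesh$vertices))
  tt <- as.matrix(read.table(paths[2], header = TRUE))
  expect_equal(unname(tt), unname(mesh$triangles))
})
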