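#' Triangulation for the SPDE representation
#'
#' Builds a structured triangulation of the partition's bounding box extended
#' by a buffer ring of width `offset` (to push boundary effects of the SPDE
#' approximation away from the study region). Vertices sit on a regular
#' lattice with spacing at most `max_edge`; each lattice cell is split into
#' two triangles along its lower-left/upper-right diagonal. The mesh carries
#' two sparse projectors: `A_points` (barycentric interpolation to arbitrary
#' points, rows sum to 1, an indicator row when a point coincides with a
#' vertex) and `A_areas` (the vertex-averaging rule `A_ig = 1/V_i` over the
#' `V_i` vertices falling inside area i, rows sum to 1).
#'
#' @param partition an [area_partition()] defining the study region.
#' @param max_edge maximum triangle edge length; default `diameter / 25`.
#' @param offset buffer width; default `0.15 * diameter`.
#' @param points optional matrix / [grid_domain()] at which to precompute
#'   `A_points`.
#' @return An object of class `spde_mesh` with elements `vertices`,
#'   `triangles`, `A_points`, `A_areas`, `fem` (lumped mass `C`, stiffness
#'   `G1`, and `G2 = G1 C^-1 G1`), and bookkeeping fields.
#' @export
build_mesh <- function(partition, max_edge = NULL, offset = NULL,
                       points = NULL) {
  bb <- partition_bbox(partition)
  diam <- sqrt((bb[2] - bb[1])^2 + (bb[4] - bb[3])^2)
  max_edge <- max_edge %||% (diam / 25)
  offset <- offset %||% (0.15 * diam)
  if (max_edge <= 0) stopf("max_edge must be positive")
  x0 <- bb[1] - offset; x1 <- bb[2] + offset
  y0 <- bb[3] - offset; y1 <- bb[4] + offset
  ## lattice spacing: at most max_edge (edge lengths are h and h*sqrt(2))
  nx <- max(2L, ceiling((x1 - x0) / max_edge))
  ny <- max(2L, ceiling((y1 - y0) / max_edge))
  hx <- (x1 - x0) / nx
  hy <- (y1 - y0) / ny
  xs <- x0 + (0:nx) * hx
  ys <- y0 + (0:ny) * hy
  vertices <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  colnames(vertices) <- c("x", "y")
  vid <- function(i, j) j * (nx + 1L) + i + 1L  # i in 0:nx, j in 0:ny
  ii <- rep(0:(nx - 1L), times = ny)
  jj <- rep(0:(ny - 1L), each = nx)
  a <- vid(ii, jj); b <- vid(ii + 1L, jj)
  cc <- vid(ii + 1L, jj + 1L); d <- vid(ii, jj + 1L)
  triangles <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  fem <- fem_matrices(vertices, triangles)
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         origin = c(x0, y0), spacing = c(hx, hy), n_cells = c(nx, ny),
         fem = fem, A_points = NULL, A_areas = NULL),
    class = "spde_mesh"
  )
  mesh$A_areas <- mesh_area_projector(mesh, partition)
  if (!is.null(points)) mesh$A_points <- mesh_point_projector(mesh, points)
  mesh
}

#' @export
print.spde_mesh <- function(x, ...) {
  cat(sprintf("<spde_mesh> %d vertices, %d triangles, spacing %.4g x %.4g\n",
              nrow(x$vertices), nrow(x$triangles), x$spacing[1], x$spacing[2]))
  invisible(x)
}

partition_bbox <- function(partition) {
  xs <- unlist(lapply(partition$polygons, function(p) p[, 1]))
  ys <- unlist(lapply(partition$polygons, function(p) p[, 2]))
  c(min(xs), max(xs), min(ys), max(ys))
}

#' Barycentric point projector
#'
#' Sparse np x G matrix whose row for point s holds the piecewise-linear
#' basis weights of the triangle containing s; rows sum to one and reduce to
#' an indicator when s is a mesh vertex.
#'
#' @param mesh an `spde_mesh`.
#' @param points matrix of coordinates or a [grid_domain()].
#' @return A `dgCMatrix`.
#' @export
mesh_point_projector <- function(mesh, points) {
  pts <- if (inherits(points, "grid_domain")) points$points else as.matrix(points)
  np <- nrow(pts)
  nx <- mesh$n_cells[1]; ny <- mesh$n_cells[2]
  hx <- mesh$spacing[1]; hy <- mesh$spacing[2]
  fx <- (pts[, 1] - mesh$origin[1]) / hx
  fy <- (pts[, 2] - mesh$origin[2]) / hy
  if (any(fx < -1e-9 | fx > nx + 1e-9 | fy < -1e-9 | fy > ny + 1e-9))
    stopf("points fall outside the mesh")
  i <- pmin(pmax(floor(fx), 0), nx - 1)
  j <- pmin(pmax(floor(fy), 0), ny - 1)
  u <- fx - i; v <- fy - j
  vid <- function(i, j) j * (nx + 1) + i + 1
  va <- vid(i, j); vb <- vid(i + 1, j); vc <- vid(i + 1, j + 1); vd <- vid(i, j + 1)
  lower <- u >= v  # triangle (a, b, c); otherwise (a, c, d)
  rows <- rep(seq_len(np), 3)
  cols <- c(va, ifelse(lower, vb, vc), ifelse(lower, vc, vd))
  wals <- c(ifelse(lower, 1 - u, 1 - v),
            ifelse(lower, u - v, u),
            ifelse(lower, v, v - u))
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = wals,
                            dims = c(np, nrow(mesh$vertices)))
  Matrix::drop0(A, tol = 1e-14)
}

## A_ig = 1/V_i over mesh vertices inside area i (inclusive of boundaries,
## lowest-index tie-break as for grid membership).
mesh_area_projector <- function(mesh, partition) {
  vg <- grid_domain(mesh$vertices, mesh$spacing)
  member <- assign_membership(vg, partition)
  nA <- n_areas(partition)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (a in seq_len(nA)) {
    idx <- which(!is.na(member) & member == a)
    if (length(idx) == 0)
      stopf("area %s contains no mesh vertices; refine the mesh",
            partition$area_ids[a])
    trip_i <- c(trip_i, rep(a, length(idx)))
    trip_j <- c(trip_j, idx)
    trip_x <- c(trip_x, rep(1 / length(idx), length(idx)))
  }
  Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                       dims = c(nA, nrow(mesh$vertices)))
}

## P1 finite-element matrices on a triangulation: lumped mass C (diagonal)
## and stiffness G1; G2 = G1 C^-1 G1 is precomputed for the SPDE precision.
fem_matrices <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  det2 <- e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1])
  area <- abs(det2) / 2
  G <- nrow(vertices)
  nt <- nrow(triangles)
  ## grad of basis k = perp(opposite edge)/(2 area); stiffness = area * g_i.g_j
  gx <- cbind(e1[, 2], e2[, 2], e3[, 2]) / det2
  gy <- cbind(-e1[, 1], -e2[, 1], -e3[, 1]) / det2
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in 1:3) {
    for (b in 1:3) {
      ii <- c(ii, triangles[, a])
      jj <- c(jj, triangles[, b])
      xx <- c(xx, area * (gx[, a] * gx[, b] + gy[, a] * gy[, b]))
    }
  }
  G1 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(G, G))
  cdiag <- numeric(G)
  for (a in 1:3) {
    tab <- tapply(rep(area / 3, 1), triangles[, a], sum)
    ## accumulate area/3 per vertex
    cdiag[as.integer(names(tab))] <- cdiag[as.integer(names(tab))] + tab
  }
  C <- Matrix::Diagonal(G, cdiag)
  Cinv <- Matrix::Diagonal(G, 1 / cdiag)
  G2 <- G1 %*% Cinv %*% G1
  list(C = C, G1 = Matrix::forceSymmetric(G1), G2 = Matrix::forceSymmetric(G2),
       c_diag = cdiag)
}

#' SPDE precision of the Matern (nu = 1) field on a mesh
#'
#' Sparse G x G precision `Q = tau^2 (kappa^4 C + 2 kappa^2 G1 + G2)` with
#' lumped mass matrix `C`, stiffness `G1` and `G2 = G1 C^-1 G1`, where
#' `tau = 1 / (kappa sigma sqrt(4 pi))` so the implied marginal variance
#' matches `sigma2_eta`. The implied correlation approximates the exact
#' Matern correlation away from the mesh boundary.
#'
#' @param mesh an `spde_mesh` from [build_mesh()].
#' @param params a [matern_params()] with `nu = 1`.
#' @return Sparse symmetric precision matrix (`dsCMatrix`).
#' @export
spde_precision <- function(mesh, params) {
  if (!isTRUE(all.equal(params$nu, 1)))
    stopf("only nu = 1 is supported by the SPDE form")
  tau2 <- spde_tau(params$kappa, params$sigma2_eta)^2
  k2 <- params$kappa^2
  Matrix::forceSymmetric(
    tau2 * (k2 * k2 * mesh$fem$C + 2 * k2 * mesh$fem$G1 + mesh$fem$G2)
  )
}

## alpha = 2, d = 2: sigma^2 = 1 / (4 pi kappa^2 tau^2)
spde_tau <- function(kappa, sigma2_eta) 1 / (kappa * sqrt(4 * pi * sigma2_eta))

spde_sigma2 <- function(kappa, tau) 1 / (4 * pi * kappa^2 * tau^2)

#' Export / import a mesh as plain delimited files
#'
#' Writes `<stem>_vertices.tsv` (x, y) and `<stem>_triangles.tsv` (v1, v2,
#' v3, 1-based) for external inspection.
#'
#' @param mesh an `spde_mesh`.
#' @param stem file path stem.
#' @return Invisibly, the two file paths.
#' @export
write_mesh <- function(mesh, stem) {
  vf <- paste0(stem, "_vertices.tsv")
  tf <- paste0(stem, "_triangles.tsv")
  utils::write.table(mesh$vertices, vf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(mesh$triangles, tf, sep = "\t", row.names = FALSE,
                     quote = FALSE, col.names = c("v1", "v2", "v3"))
  invisible(c(vf, tf))
}
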