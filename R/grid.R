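#' Prediction grids
#'
#' A `grid_domain` is the target support of the disaggregation: the cell
#' centres of a regular raster, the cell edge lengths, and (once assigned) the
#' membership of each cell in the areal partition.
#'
#' @param points np x 2 matrix of cell-centre coordinates.
#' @param resolution numeric length-2 cell edge lengths `c(dx, dy)`.
#' @param membership optional integer vector mapping cells to areas.
#' @return An object of class `grid_domain`.
#' @export
grid_domain <- function(points, resolution, membership = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("points must have two columns")
  if (anyDuplicated(points)) stopf("grid points must be pairwise distinct")
  structure(
    list(points = points, resolution = resolution, membership = membership),
    class = "grid_domain"
  )
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("<grid_domain> %d points, resolution %.4g x %.4g\n",
              nrow(x$points), x$resolution[1], x$resolution[2]))
  invisible(x)
}

#' Build a regular prediction grid
#'
#' Lays `n_x` by `n_y` cell centres on a regular lattice covering `bbox`,
#' e.g. the 60 x 60 (np = 3600) raster over the unit square used in the
#' simulation study.
#'
#' @param n_x,n_y number of cells along x and y (>= 1).
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`.
#' @return A [grid_domain()] with `n_x * n_y` points ordered row-major from
#'   the lower-left cell.
#' @examples
#' g <- build_grid(60, 60)
#' nrow(g$points)  # 3600
#' @export
build_grid <- function(n_x, n_y, bbox = c(0, 1, 0, 1)) {
  if (n_x < 1 || n_y < 1 || n_x != round(n_x) || n_y != round(n_y))
    stopf("n_x and n_y must be positive integers")
  dx <- (bbox[2] - bbox[1]) / n_x
  dy <- (bbox[4] - bbox[3]) / n_y
  if (dx <= 0 || dy <= 0) stopf("degenerate bounding box")
  xs <- bbox[1] + (seq_len(n_x) - 0.5) * dx
  ys <- bbox[3] + (seq_len(n_y) - 0.5) * dy
  pts <- cbind(rep(xs, times = n_y), rep(ys, each = n_x))
  colnames(pts) <- c("x", "y")
  grid_domain(pts, c(dx, dy))
}

#' Median pairwise distance between grid points
#'
#' The quantity `m` entering the prior mean `log(8/m)` of the log Matern
#' scale. Exact for up to `max_exact` points; above that a seeded subsample of
#' `max_exact` points is used.
#'
#' @param grid a [grid_domain()] or an np x 2 coordinate matrix.
#' @param max_exact exact computation threshold (default 2000).
#' @param seed integer seed for the subsample (only used above the threshold).
#' @return Median Euclidean distance.
#' @export
median_pairwise_distance <- function(grid, max_exact = 2000, seed = 1L) {
  pts <- if (inherits(grid, "grid_domain")) grid$points else as.matrix(grid)
  n <- nrow(pts)
  if (n < 2) stopf("need at least two points")
  if (n > max_exact) {
    idx <- local({
      rng <- get_rng_state()
      on.exit(restore_rng_state(rng))
      set.seed(seed)
      sample.int(n, max_exact)
    })
    pts <- pts[idx, , drop = FALSE]
  }
  median(dist(pts))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Covariate stacks at both supports
#'
#' Bundles the grid-level design matrix (intercept first), its block-averaged
#' areal counterpart, and covariate names. The areal design is recomputed from
#' the grid values so the two supports are always consistent.
#'
#' @param X_grid np x k design matrix including an intercept column of ones.
#' @param membership integer area index per grid cell.
#' @param n_areas number of areas.
#' @param names optional covariate names (defaults to colnames).
#' @return An object of class `covariate_stack` with elements `X_grid`,
#'   `X_area`, `names`.
#' @export
covariate_stack <- function(X_grid, membership, n_areas, names = NULL) {
  X_grid <- as.matrix(X_grid)
  if (!all(X_grid[, 1] == 1)) stopf("first column must be an intercept of ones")
  nm <- names %||% colnames(X_grid) %||%
    c("intercept", sprintf("x%d", seq_len(ncol(X_grid) - 1)))
  colnames(X_grid) <- nm
  X_area <- block_average(X_grid, membership, n_areas)
  structure(list(X_grid = X_grid, X_area = X_area, names = nm),
            class = "covariate_stack")
}

#' Areal observations
#'
#' Vaccinated counts `Y` and sample sizes `N` per area, with a logical mask of
#' observed areas; unobserved areas (e.g. provinces excluded from a survey)
#' contribute nothing to the likelihood but still receive posterior estimates.
#'
#' @param Y numeric vector of success counts (NA where unobserved).
#' @param N numeric vector of sample sizes (NA where unobserved).
#' @param observed logical mask; defaults to `!is.na(Y) & !is.na(N)`.
#' @return An object of class `areal_counts`.
#' @export
areal_counts <- function(Y, N, observed = NULL) {
  if (length(Y) != length(N)) stopf("Y and N must have equal length")
  observed <- observed %||% (!is.na(Y) & !is.na(N))
  if (any(observed & (is.na(Y) | is.na(N))))
    stopf("observed areas must have nonmissing Y and N")
  if (any(N[observed] < 1)) stopf("observed areas need N >= 1")
  if (any(Y[observed] < 0 | Y[observed] > N[observed]))
    stopf("need 0 <= Y <= N for observed areas")
  structure(list(Y = Y, N = N, observed = observed), class = "areal_counts")
}
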