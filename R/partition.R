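#' Areal partitions
#'
#' An `area_partition` holds the areal support of the disaggregation model:
#' ordered area identifiers, one planar polygon per area, the binary
#' neighbourhood matrix `W` (shared border => neighbour) and the area measures
#' `|A_i|` in squared coordinate units.
#'
#' @param area_ids character or integer vector of area labels.
#' @param polygons list of polygons; each polygon is a two-column matrix of
#'   vertex coordinates (closed implicitly, last vertex need not repeat the
#'   first).
#' @param W nA x nA binary symmetric adjacency matrix with zero diagonal.
#' @param sizes optional numeric vector of area measures; computed from the
#'   polygons (shoelace formula) when omitted.
#' @return An object of class `area_partition`.
#' @seealso [build_unit_square_partition()], [rect_partition()]
#' @export
area_partition <- function(area_ids, polygons, W, sizes = NULL) {
  nA <- length(area_ids)
  if (length(polygons) != nA) stopf("need one polygon per area")
  W <- as.matrix(W)
  if (!all(dim(W) == c(nA, nA))) stopf("W must be %d x %d", nA, nA)
  if (!isSymmetric(unname(W))) stopf("W must be symmetric")
  if (any(diag(W) != 0)) stopf("W must have a zero diagonal")
  if (!all(W %in% c(0, 1))) stopf("W must be binary")
  if (is.null(sizes)) sizes <- vapply(polygons, polygon_area, numeric(1))
  if (any(sizes <= 0)) stopf("area measures must be positive")
  structure(
    list(area_ids = area_ids, polygons = polygons, W = W, sizes = sizes),
    class = "area_partition"
  )
}

#' @export
print.area_partition <- function(x, ...) {
  cat(sprintf(
    "<area_partition> %d areas, %d neighbour pairs, total size %.4g\n",
    length(x$area_ids), sum(x$W) / 2, sum(x$sizes)
  ))
  invisible(x)
}

n_areas <- function(partition) length(partition$area_ids)

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rectangular tiling of a bounding box
#'
#' Partitions a rectangle into `n_x` by `n_y` congruent rectangular areas with
#' rook (shared-edge) adjacency. Areas are ordered row-major from the lower
#' left corner.
#'
#' @param n_x,n_y number of areas along x and y.
#' @param bbox numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return An [area_partition()].
#' @export
rect_partition <- function(n_x, n_y, bbox = c(0, 1, 0, 1)) {
  if (n_x < 1 || n_y < 1 || n_x != round(n_x) || n_y != round(n_y))
    stopf("n_x and n_y must be positive integers")
  dx <- (bbox[2] - bbox[1]) / n_x
  dy <- (bbox[4] - bbox[3]) / n_y
  if (dx <= 0 || dy <= 0) stopf("degenerate bounding box")
  nA <- n_x * n_y
  polygons <- vector("list", nA)
  ids <- character(nA)
  for (j in seq_len(n_y)) {
    for (i in seq_len(n_x)) {
      a <- (j - 1) * n_x + i
      x0 <- bbox[1] + (i - 1) * dx; x1 <- x0 + dx
      y0 <- bbox[3] + (j - 1) * dy; y1 <- y0 + dy
      polygons[[a]] <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
      ids[a] <- sprintf("A%03d", a)
    }
  }
  W <- matrix(0, nA, nA)
  for (j in seq_len(n_y)) {
    for (i in seq_len(n_x)) {
      a <- (j - 1) * n_x + i
      if (i < n_x) W[a, a + 1] <- W[a + 1, a] <- 1
      if (j < n_y) W[a, a + n_x] <- W[a + n_x, a] <- 1
    }
  }
  area_partition(ids, polygons, W, rep(dx * dy, nA))
}

#' Square-area partition of the unit square
#'
#' The simulation-study areal support: `n_side`^2 congruent square areas
#' tiling `[0,1]^2` with rook adjacency.
#'
#' @param n_side number of areas along each side (>= 1).
#' @return An [area_partition()] with `n_side^2` areas.
#' @examples
#' p <- build_unit_square_partition(3)
#' rowSums(p$W)  # corners have 2 neighbours, centre has 4
#' @export
build_unit_square_partition <- function(n_side) {
  if (length(n_side) != 1 || n_side < 1 || n_side != round(n_side))
    stopf("n_side must be a positive integer")
  rect_partition(n_side, n_side, c(0, 1, 0, 1))
}

## Ray-casting point-in-polygon; boundary points count as inside so that the
## lowest-index tie-break in assign_membership() is well defined.
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  jj <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- x[jj[e]]; y1 <- y[jj[e]]; x2 <- x[e]; y2 <- y[e]
    ## points lying on this edge segment
    d <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    on_seg <- abs(d) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Assign grid points to areas
#'
#' Maps each grid point to the area whose polygon contains its cell centre.
#' Points falling on a shared boundary are assigned to the lowest area index;
#' points outside every polygon are flagged `NA` and excluded from the
#' likelihood downstream.
#'
#' @param grid a [grid_domain()].
#' @param partition an [area_partition()].
#' @return Integer vector of area indices (NA outside the partition).
#' @export
assign_membership <- function(grid, partition) {
  pts <- grid$points
  membership <- rep(NA_integer_, nrow(pts))
  for (a in seq_along(partition$polygons)) {
    todo <- is.na(membership)
    if (!any(todo)) break
    hit <- point_in_polygon(pts[todo, 1], pts[todo, 2], partition$polygons[[a]])
    membership[which(todo)[hit]] <- a
  }
  membership
}

#' Block average a gridded matrix onto areas
#'
#' Row `i` of the result is the unweighted mean of the rows of `X_grid` whose
#' grid cell belongs to area `i` (grid cells are equal-area, so the unweighted
#' mean is the discrete block average `|A_i|^-1 \int_{A_i} x(s) ds`). Optional
#' weights (e.g. population) give a weighted variant for irregular supports.
#'
#' @param X_grid numeric matrix (or vector) with one row per grid point.
#' @param membership integer area index per grid point (NA = outside).
#' @param n_areas number of areas; defaults to `max(membership)`.
#' @param weights optional nonnegative per-cell weights.
#' @return `n_areas` x `ncol(X_grid)` matrix of block averages.
#' @export
block_average <- function(X_grid, membership, n_areas = NULL, weights = NULL) {
  X_grid <- as.matrix(X_grid)
  if (nrow(X_grid) != length(membership))
    stopf("membership length must match rows of X_grid")
  nA <- n_areas %||% max(membership, na.rm = TRUE)
  w <- weights %||% rep(1, nrow(X_grid))
  if (any(w < 0)) stopf("weights must be nonnegative")
  out <- matrix(NA_real_, nA, ncol(X_grid))
  for (a in seq_len(nA)) {
    idx <- which(!is.na(membership) & membership == a)
    if (length(idx) == 0) stopf("area %d contains no grid points", a)
    wa <- w[idx] / sum(w[idx])
    out[a, ] <- colSums(X_grid[idx, , drop = FALSE] * wa)
  }
  colnames(out) <- colnames(X_grid)
  out
}
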