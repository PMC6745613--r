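#' Read areal count data from CSV
#'
#' Expects columns `area_id`, `Y`, `N`; empty or missing `Y`/`N` mark
#' unobserved areas (they receive posterior estimates but no likelihood).
#' Rows are reordered to match `area_ids` when given.
#'
#' @param path CSV path.
#' @param area_ids optional ordering of area identifiers.
#' @return An [areal_counts()] with attribute `area_id`.
#' @export
read_areal_csv <- function(path, area_ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "Y", "N")
  if (!all(need %in% names(df)))
    stopf("areal CSV must have columns: %s", paste(need, collapse = ", "))
  if (!is.null(area_ids)) {
    idx <- match(area_ids, df$area_id)
    if (anyNA(idx)) stopf("areal CSV is missing areas: %s",
                          paste(area_ids[is.na(idx)], collapse = ", "))
    df <- df[idx, ]
  }
  out <- areal_counts(as.numeric(df$Y), as.numeric(df$N))
  attr(out, "area_id") <- df$area_id
  out
}

#' Read area boundaries from GeoJSON
#'
#' Reads one feature per area (Polygon, or MultiPolygon taking the largest
#' ring) and derives rook-style adjacency by matching shared polygon edges
#' exactly; supply `W` to override for boundary files whose neighbouring
#' polygons do not share identical vertex chains. All features must be in
#' one planar coordinate system; no reprojection is attempted.
#'
#' @param path GeoJSON file path.
#' @param id_property feature property holding the area identifier.
#' @param W optional adjacency matrix overriding edge matching.
#' @return An [area_partition()].
#' @export
read_boundaries_geojson <- function(path, id_property = "id", W = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stopf("not a GeoJSON FeatureCollection")
  ids <- character(length(feats))
  polygons <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ids[i] <- as.character(f$properties[[id_property]] %||% i)
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = {
        rings <- lapply(geom$coordinates, function(pp) pp[[1]])
        sizes <- vapply(rings, function(r)
          polygon_area(do.call(rbind, lapply(r, unlist))), numeric(1))
        rings[[which.max(sizes)]]
      },
      stopf("unsupported geometry type: %s", geom$type))
    m <- do.call(rbind, lapply(ring, unlist))
    ## drop a closing vertex that repeats the first
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polygons[[i]] <- m
  }
  W <- W %||% adjacency_from_edges(polygons)
  area_partition(ids, polygons, W)
}

## two areas are neighbours when they share at least one polygon edge
## (identical vertex pairs up to orientation and rounding)
adjacency_from_edges <- function(polygons, digits = 9) {
  edge_keys <- lapply(polygons, function(p) {
    n <- nrow(p)
    nxt <- c(2:n, 1)
    a <- round(p, digits); b <- round(p[nxt, , drop = FALSE], digits)
    lo <- pmin(a, b); hi <- pmax(a, b)
    paste(lo[, 1], lo[, 2], hi[, 1], hi[, 2], sep = "|")
  })
  nA <- length(polygons)
  W <- matrix(0, nA, nA)
  for (i in seq_len(nA - 1)) {
    for (j in (i + 1):nA) {
      if (any(edge_keys[[i]] %in% edge_keys[[j]])) W[i, j] <- W[j, i] <- 1
    }
  }
  W
}

#' Read a gridded layer from a delimited matrix file
#'
#' Plain-text raster: whitespace- or comma-delimited numeric matrix, one row
#' per raster row, northernmost row first (standard raster order). Values
#' equal to `nodata` become NA. Returns cell values in the row-major
#' (lower-left first) order used by [build_grid()].
#'
#' @param path file path.
#' @param nodata value to treat as missing (default none).
#' @param sep field separator (default any whitespace).
#' @return Numeric vector of cell values plus attributes `nrow`, `ncol`.
#' @export
read_grid_matrix <- function(path, nodata = NULL, sep = "") {
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  if (!is.null(nodata)) m[m == nodata] <- NA
  ## flip: file rows run north->south, grid order runs south->north
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  v <- as.numeric(t(m))
  attr(v, "nrow") <- nrow(m); attr(v, "ncol") <- ncol(m)
  v
}

#' Read a single-band TIFF covariate layer
#'
#' Reads pixel values from a (Geo)TIFF via the `tiff` package, ignoring any
#' georeferencing tags; the layer must already be aligned to the prediction
#' grid (nearest-neighbour resampling upstream). Requires the suggested
#' `tiff` package.
#'
#' @param path TIFF path.
#' @param nodata value to treat as missing.
#' @return Numeric vector in grid order, as [read_grid_matrix()].
#' @export
read_grid_tiff <- function(path, nodata = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required to read TIFF layers")
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!is.null(nodata)) m[m == nodata] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  v <- as.numeric(t(m))
  attr(v, "nrow") <- nrow(m); attr(v, "ncol") <- ncol(m)
  v
}

#' Nearest-neighbour resample of a gridded layer
#'
#' Aligns a covariate layer given on one regular raster to the prediction
#' grid by nearest-neighbour lookup (covariate preprocessing convention;
#' both rasters must share the coordinate system).
#'
#' @param values numeric vector of source cell values in grid order.
#' @param src_grid source [grid_domain()].
#' @param dst_grid destination [grid_domain()].
#' @return Numeric vector of resampled values on `dst_grid`.
#' @export
resample_nearest <- function(values, src_grid, dst_grid) {
  sp <- src_grid$points; dp <- dst_grid$points
  xs <- sort(unique(sp[, 1])); ys <- sort(unique(sp[, 2]))
  ix <- pmin(pmax(round((dp[, 1] - xs[1]) / (xs[2] - xs[1])) + 1, 1), length(xs))
  iy <- pmin(pmax(round((dp[, 2] - ys[1]) / (ys[2] - ys[1])) + 1, 1), length(ys))
  ## source order is row-major from lower-left
  values[(iy - 1) * length(xs) + ix]
}

#' Convert decimal degrees to kilometres
#'
#' Presentation utility for reporting spatial ranges fitted in raw degrees
#' (1 degree is taken as 111.32 km); the model itself always works in the
#' native coordinates of its inputs.
#'
#' @param degrees numeric distances in decimal degrees.
#' @return Distances in kilometres.
#' @export
degrees_to_km <- function(degrees) degrees * 111.32

#' Bundled weighted survey summaries
#'
#' Returns the weighted national summaries (children surveyed and vaccinated,
#' by country and vaccine) bundled with the package, used in the worked
#' examples of [coverage_percent()].
#'
#' @return Data frame with columns country, vaccine, children, vaccinated,
#'   printed_pct.
#' @export
dhs_summary_data <- function() {
  read.csv(system.file("extdata", "dhs_vaccination_summary.csv",
                       package = "disaggmap"), stringsAsFactors = FALSE)
}
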