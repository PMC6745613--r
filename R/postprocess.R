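#' Aggregate grid predictions to reporting units
#'
#' Averages the per-cell posterior mean coverage over the grid cells within
#' each unit (e.g. districts), the standard change-of-support summary used
#' when assessing targets set at an administrative level. A population-
#' weighted variant is available via `weights`.
#'
#' @param pred a `grid_prediction` (or a numeric vector of cell values).
#' @param unit_membership integer unit index per grid cell (NA = outside).
#' @param n_units number of units; defaults to `max(unit_membership)`.
#' @param weights optional nonnegative per-cell weights (e.g. population).
#' @return Numeric vector of per-unit mean coverage.
#' @export
aggregate_to_units <- function(pred, unit_membership, n_units = NULL,
                               weights = NULL) {
  vals <- if (inherits(pred, "grid_prediction")) pred$mean else as.numeric(pred)
  drop(block_average(vals, unit_membership, n_units, weights))
}

#' Coldspot classification of a predicted coverage surface
#'
#' Classifies each grid cell by the within-map quantiles of the posterior
#' mean coverage: the lowest 20%, lowest 50% and lowest 80% of coverage
#' values (classes are nested; cells at or below a cutpoint belong to the
#' class, ties inclusive). Cutpoints use the type-7 quantile convention.
#'
#' @param pred a `grid_prediction` or numeric vector of cell coverage values.
#' @param quantiles the three class quantiles (default `c(0.2, 0.5, 0.8)`).
#' @return An object of class `coldspot_map`: `class` (factor with levels
#'   lowest20, lowest50, lowest80, above) and `cutpoints`.
#' @export
coldspot_classes <- function(pred, quantiles = c(0.2, 0.5, 0.8)) {
  vals <- if (inherits(pred, "grid_prediction")) pred$mean else as.numeric(pred)
  if (length(vals) == 0) stopf("empty prediction")
  if (is.unsorted(quantiles)) stopf("quantiles must be nondecreasing")
  cut_q <- quantile(vals, quantiles, names = FALSE, type = 7)
  labels <- paste0("lowest", round(100 * quantiles))
  cls <- rep("above", length(vals))
  for (i in rev(seq_along(cut_q))) cls[vals <= cut_q[i]] <- labels[i]
  structure(
    list(class = factor(cls, levels = c(labels, "above")),
         cutpoints = setNames(cut_q, labels)),
    class = "coldspot_map"
  )
}

#' @export
print.coldspot_map <- function(x, ...) {
  cat("<coldspot_map> cutpoints:",
      paste(sprintf("%s=%.3f", names(x$cutpoints), x$cutpoints),
            collapse = ", "), "\n")
  print(table(x$class))
  invisible(x)
}

#' Coverage-target attainment of reporting units
#'
#' Flags units whose mean coverage reaches the target (default the 80%
#' all-vaccine goal; the threshold is inclusive) and summarizes the
#' percentage of units attaining it.
#'
#' @param unit_means per-unit mean coverage in [0, 1].
#' @param threshold attainment threshold (default 0.80).
#' @return List with `attained` (logical flags) and `percent_attained`.
#' @export
threshold_attainment <- function(unit_means, threshold = 0.80) {
  if (any(unit_means < 0 | unit_means > 1, na.rm = TRUE))
    stopf("unit means must lie in [0, 1]")
  flags <- unit_means >= threshold
  list(attained = flags,
       percent_attained = 100 * mean(flags, na.rm = TRUE))
}

#' Unvaccinated-count integration with a population surface
#'
#' Combines predicted coverage with a matching population raster:
#' `count = sum(pop_i * (1 - p_i))` at cell, unit or national level. When the
#' coverage surface refers to a proxy age group (e.g. 12-23 months standing
#' in for under-5 coverage), the output records that in its metadata.
#'
#' @param pred a `grid_prediction` or numeric vector of cell coverage.
#' @param population numeric per-cell population counts aligned to the grid.
#' @param level `"cell"`, `"unit"` or `"national"`.
#' @param unit_membership required for `level = "unit"`.
#' @param n_units number of units for `level = "unit"`.
#' @param proxy_note metadata string describing any age-group proxy.
#' @return Numeric vector (cell/unit) or scalar (national) of expected
#'   unvaccinated counts, with attribute `proxy`.
#' @export
unvaccinated_counts <- function(pred, population,
                                level = c("national", "unit", "cell"),
                                unit_membership = NULL, n_units = NULL,
                                proxy_note = "coverage in 12-23-month-olds used as proxy") {
  level <- match.arg(level)
  p <- if (inherits(pred, "grid_prediction")) pred$mean else as.numeric(pred)
  if (length(population) != length(p))
    stopf("population raster is not aligned to the prediction grid")
  cell <- population * (1 - p)
  out <- switch(level,
    cell = cell,
    national = sum(cell),
    unit = {
      if (is.null(unit_membership)) stopf("unit_membership required")
      nU <- n_units %||% max(unit_membership, na.rm = TRUE)
      vapply(seq_len(nU), function(u)
        sum(cell[!is.na(unit_membership) & unit_membership == u]),
        numeric(1))
    })
  attr(out, "proxy") <- proxy_note
  out
}
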