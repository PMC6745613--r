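#' Grid predictions from a fitted disaggregation model
#'
#' Propagates the posterior draws of `(beta, SPDE weights, phi)` through the
#' grid-level predictor `logit(p(s)) = x(s)' beta + eta(s) + phi_{A(s)}` to
#' per-cell posterior means, standard deviations and equal-tailed 95%
#' intervals of `p(s)` (computed on the probability scale from draws, which
#' coincides with transforming logit-scale quantiles). Area-level estimates
#' use the area predictor with block-averaged covariates and vertex-averaged
#' GP, and are produced for all areas including unobserved ones.
#'
#' @param object a `disagg_fit`.
#' @param cov optional [covariate_stack()] (defaults to the one used to fit).
#' @param grid optional [grid_domain()] (defaults to the fitted grid).
#' @param membership optional membership vector.
#' @param level credible level (default 0.95).
#' @param ... unused.
#' @return An object of class `grid_prediction` with fields `mean`, `sd`,
#'   `lower95`, `upper95` (np-vectors), `outside` (logical flag for cells
#'   outside the partition), and `area_estimates` (data frame with posterior
#'   mean/sd/interval per area plus the observed proportion).
#' @export
predict.disagg_fit <- function(object, cov = NULL, grid = NULL,
                               membership = NULL, level = 0.95, ...) {
  ctx <- object$ctx
  cov <- cov %||% ctx$cov
  same_grid <- is.null(grid)
  grid <- grid %||% ctx$grid
  membership <- membership %||% (if (same_grid) ctx$membership else
    assign_membership(grid, ctx$partition))
  A_pts <- if (same_grid) ctx$mesh$A_points else
    mesh_point_projector(ctx$mesh, grid)
  zs <- object$z_samples
  k <- ctx$k; G <- ctx$G; nA <- ctx$nA
  beta_s <- zs[seq_len(k), , drop = FALSE]
  w_s <- zs[k + seq_len(G), , drop = FALSE]
  phi_s <- zs[k + G + seq_len(nA), , drop = FALSE]
  ok <- !is.na(membership)
  phi_cell <- matrix(0, nrow(cov$X_grid), ncol(zs))
  phi_cell[ok, ] <- phi_s[membership[ok], , drop = FALSE]
  lin <- cov$X_grid %*% beta_s + as.matrix(A_pts %*% w_s) + phi_cell
  p <- invlogit(lin)
  qs <- row_quantiles(p, c((1 - level) / 2, 1 - (1 - level) / 2))
  pm <- rowMeans(p)
  psd <- row_sds(p)
  ## area-level predictor for every area (missing areas included)
  lin_a <- cov$X_area %*% beta_s + as.matrix(ctx$mesh$A_areas %*% w_s) + phi_s
  pa <- invlogit(lin_a)
  qa <- row_quantiles(pa, c((1 - level) / 2, 1 - (1 - level) / 2))
  area_estimates <- data.frame(
    area_id = ctx$partition$area_ids,
    observed = ctx$data$observed,
    obs_proportion = ifelse(ctx$data$observed,
                            ctx$data$Y / ctx$data$N, NA_real_),
    mean = rowMeans(pa), sd = row_sds(pa),
    lower = qa[, 1], upper = qa[, 2]
  )
  structure(
    list(mean = pm, sd = psd, lower95 = qs[, 1], upper95 = qs[, 2],
         outside = !ok, level = level, area_estimates = area_estimates,
         grid = grid),
    class = "grid_prediction"
  )
}

#' @export
print.grid_prediction <- function(x, ...) {
  cat(sprintf(
    "<grid_prediction> %d cells (%d outside partition), mean p in [%.3f, %.3f]\n",
    length(x$mean), sum(x$outside), min(x$mean), max(x$mean)))
  invisible(x)
}

row_quantiles <- function(m, probs) {
  t(apply(m, 1, quantile, probs = probs, names = FALSE, type = 7))
}

row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' Equal-tailed credible interval
#'
#' For a vector (or matrix, row-wise) of posterior draws, the equal-tailed
#' interval at the given level; for a Gaussian representation
#' `list(mean =, sd =)` the normal-quantile interval `mean +/- z sd`,
#' optionally on the logit scale followed by the inverse-logit transform
#' (guaranteeing bounds within [0, 1]).
#'
#' @param x numeric vector, matrix of draws (rows = quantities), or
#'   `list(mean =, sd =)`.
#' @param level credible level in (0, 1).
#' @param logit_scale for the Gaussian form: interpret mean/sd on the logit
#'   scale and back-transform the endpoints.
#' @return Numeric vector `c(lower, upper)` or a two-column matrix.
#' @export
credible_interval <- function(x, level = 0.95, logit_scale = FALSE) {
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  a <- (1 - level) / 2
  if (is.list(x) && !is.null(x$mean) && !is.null(x$sd)) {
    z <- qnorm(1 - a)
    lo <- x$mean - z * x$sd; hi <- x$mean + z * x$sd
    if (logit_scale) { lo <- invlogit(lo); hi <- invlogit(hi) }
    return(cbind(lower = lo, upper = hi))
  }
  if (is.matrix(x)) {
    if (ncol(x) == 0) stopf("empty draws")
    out <- row_quantiles(x, c(a, 1 - a))
    colnames(out) <- c("lower", "upper")
    return(out)
  }
  if (length(x) == 0) stopf("empty draws")
  out <- quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = out[1], upper = out[2])
}

#' Export a fit summary as CSV
#'
#' Writes the hyperparameter and coefficient summary table
#' (parameter, mean, sd, q025, q975).
#'
#' @param fit a `disagg_fit`.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_fit_summary <- function(fit, path) {
  write.csv(fit$theta_summary, path, row.names = FALSE)
  invisible(path)
}

#' Export grid predictions as CSV
#'
#' One row per grid cell: coordinates, posterior mean, sd, and interval
#' bounds; cells outside the partition are flagged.
#'
#' @param pred a `grid_prediction`.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_prediction_csv <- function(pred, path) {
  df <- data.frame(
    x = pred$grid$points[, 1], y = pred$grid$points[, 2],
    mean = pred$mean, sd = pred$sd,
    lower95 = pred$lower95, upper95 = pred$upper95,
    outside = pred$outside
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
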