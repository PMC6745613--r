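# disaggmap

High-resolution mapping of vaccination coverage (or any binomial indicator)
from **areal survey data alone**. Where geolocated cluster data are
unavailable — surveys released only as province-level totals — `disaggmap`
fits a joint binomial spatial regression that disaggregates the areal counts
to a fine prediction grid with full posterior uncertainty, then turns the
maps into decision products: district aggregates, coverage coldspots,
target-attainment flags and unvaccinated-count estimates.

## The model

For areas `A_1..A_nA` with weighted counts `Y_i` of `N_i` children and grid
points `s_1..s_np`:

    Y_i ~ Binomial(N_i, p_i)
    logit(p_i)    = x̃_i'β + |A_i|⁻¹ ∫_{A_i} η(s) ds + φ_i      (areas)
    logit(p(s_i)) = x_i'β + η(s_i) + φ_{A_i}                    (grid)

* `β` — regression coefficients shared across supports; the areal
  covariates `x̃_i` are block averages of the gridded layers.
* `η` — stationary Matérn (ν = 1) Gaussian process, variance `σ_η²`, scale
  `κ`, practical range `r = √8/κ`; represented for fitting as an SPDE-type
  GMRF on a triangulation (sparse precision, barycentric point projector,
  `1/V_i` vertex-averaging area projector).
* `φ` — Leroux CAR field on the areal adjacency graph:
  `φ ~ N(0, σ_φ² Q⁻¹(W))`, `Q(W) = ρ(diag(W1) − W) + (1 − ρ)I`.

Inference: an inner–outer **Laplace** engine (sparse Newton on the latent
field inside a simplex search over transformed hyperparameters) and a
one-block **MCMC** engine (joint hyperparameter random walk + conditional
Gaussian latent proposal), bound together by a cross-engine agreement test.

## Worked example

Fit the bundled synthetic 3×3-province fixture (one province unobserved, as
when a survey cannot reach an area) and map coverage on its 12×12 grid:

```r
library(disaggmap)
fx <- function(f) system.file("extdata", f, package = "disaggmap")

partition <- read_boundaries_geojson(fx("fixture_boundaries_3x3.geojson"))
counts    <- read_areal_csv(fx("fixture_areal_3x3_synthetic.csv"),
                            partition$area_ids)
x1 <- read_grid_matrix(fx("fixture_cov_x1_synthetic.txt"))
x2 <- read_grid_matrix(fx("fixture_cov_x2_synthetic.txt"))
grid <- build_grid(12, 12)
grid$membership <- assign_membership(grid, partition)
cov <- covariate_stack(cbind(intercept = 1, x1 = x1, x2 = x2),
                       grid$membership, 9)

fit  <- disagg_fit(counts, cov, partition, grid, seed = 3,
                   controls = list(max_edge = 0.12))
pred <- predict(fit)
pred
#> <grid_prediction> 144 cells (0 outside partition), mean p in [0.235, 0.719]
subset(pred$area_estimates, !observed)
#>   area_id observed obs_proportion  mean   sd lower upper
#> 5    A005    FALSE             NA 0.535 0.11 0.305 0.746
```

The unobserved province gets a full posterior estimate (here mean coverage
0.535 with a 95% interval 0.305–0.746) borrowed through the spatial fields
and covariates, and is flagged `observed = FALSE`. Downstream:

```r
cold  <- coldspot_classes(pred)             # lowest 20/50/80% coverage cells
units <- aggregate_to_units(pred, grid$membership)
threshold_attainment(units, 0.80)           # who meets the 80% target
unvaccinated_counts(pred, population, "unit",
                    unit_membership = grid$membership)
```

A simulation-study harness reproduces the unit-square evaluation design
(`sim_setting()`, `run_study()`), and a command-line front end wraps the
pipelines (`Rscript inst/cli/disaggmap.R study --seed 1 --out results/`).

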