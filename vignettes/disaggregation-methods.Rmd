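---
title: "Area-to-point disaggregation of binomial coverage data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-to-point disaggregation of binomial coverage data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disaggmap)
```

## The problem

Vaccination coverage (and many other health indicators) is often reported
only as areal summaries — the number of children surveyed, $N_i$, and the
number vaccinated, $Y_i$, per province — while programme planning needs
high-resolution maps. `disaggmap` implements a joint binomial spatial
regression that links the areal observations to a fine prediction grid and
produces per-cell posterior coverage estimates with uncertainty. This is a
change-of-support (area-to-point) problem: the data live on polygons, the
predictions on raster cells, and nothing is observed at the grid level.

## The model

With areas $A_1, \dots, A_{n_A}$ and grid points $s_1, \dots, s_{n_p}$:

$$
\begin{aligned}
Y_i &\sim \mathrm{Binomial}(N_i, p_i), \qquad i = 1, \dots, n_A,\\
\operatorname{logit}(p_i) &= \tilde{\mathbf x}_i'\boldsymbol\beta +
  |A_i|^{-1}\!\!\int_{A_i}\eta(s)\,ds + \phi_i
  \qquad \text{(areas)},\\
\operatorname{logit}(p(s_i)) &= \mathbf x_i'\boldsymbol\beta + \eta(s_i) +
  \phi_{A_i} \qquad \text{(grid cells)},
\end{aligned}
$$

where $\tilde{\mathbf x}_i$ are block averages of the gridded covariates
over area $i$ (intercept first), $\eta$ is a zero-mean stationary Gaussian
process with Matérn covariance (smoothness $\nu = 1$, marginal variance
$\sigma_\eta^2$, scale $\kappa$, practical range $r = \sqrt{8\nu}/\kappa$ —
the distance at which correlation has fallen to $\approx 0.14$), and
$\boldsymbol\phi$ is a Leroux conditional autoregressive field on the areal
graph, $\boldsymbol\phi \sim N(0, \sigma_\phi^2 Q^{-1}(W))$ with
$Q(W) = \rho(\operatorname{diag}(W\mathbf 1) - W) + (1-\rho)I$. The three
devices that meld the two supports are the shared coefficients
$\boldsymbol\beta$, the area-averaging of $\eta$, and the lookup
$\phi_{A_i}$ of each cell's area effect.

For scalability $\eta$ is represented as an SPDE-type Gauss–Markov random
field: piecewise-linear basis functions on a triangulation, sparse precision
$Q_\eta = \tau^2(\kappa^4 C + 2\kappa^2 G_1 + G_1 C^{-1} G_1)$ with
mass-lumped $C$ and stiffness $G_1$, and
$\tau = 1/(\kappa\sigma_\eta\sqrt{4\pi})$ so the implied marginal variance is
$\sigma_\eta^2$. Point values use barycentric interpolation (`A_points`);
area averages use the vertex rule $A_{ig} = 1/V_i$ over the $V_i$ mesh
vertices inside area $i$ (`A_areas`). The package also carries a dense exact
Matérn representation (`gp_sampler()`) used for simulation and as the oracle
in tests; the fitted latent field always uses the sparse form, and a test
binds the two (correlation sup-discrepancy below 0.05 on a fine mesh).

### Mesh

The default mesh is a structured lattice triangulation of the bounding box
extended by a buffer ring of width $0.15\times$ the domain diameter, with
uniform vertex spacing of diameter/25 everywhere (each lattice cell is split
into two triangles). For rectangular domains a structured mesh matches the
quality of a constrained Delaunay triangulation while keeping the projector
construction exact and fast; using the interior resolution throughout the
buffer is slightly conservative (finer than needed there). The buffer
mitigates the variance inflation of the Neumann boundary condition of the
SPDE; the implied variance is within 10% of $\sigma_\eta^2$ at vertices well
inside the domain.

## Priors and parameterization

Following the internal conventions of latent Gaussian software:
$\boldsymbol\beta \sim N(0, 10^5 I)$ (intercept included); CAR precision
$1/\sigma_\phi^2 \sim \mathrm{Gamma}(1, 0.01)$ (simulation-study mode swaps
in $\mathrm{Gamma}(5, 1)$); $\operatorname{logit}\rho \sim N(0, 0.45)$ — the
0.45 is read as a **variance** (variance and precision parameterizations of
this prior are easy to confuse, so the choice is made explicit and exposed
as `prior_spec(rho_logit_normal=)`); $\log\kappa \sim N(\log(8/m), 1)$ with $m$
the median pairwise distance between prediction points; and
$\log\tau \sim N(0, 1)$, a vague log-normal on $\sigma_\eta^2$ given
$\kappa$. Inference works on the transformed scale
$(\log\tau, \log\kappa, \log(1/\sigma_\phi^2), \operatorname{logit}\rho)$.

## Inference engines

`disagg_fit(engine = "laplace")` (default) nests Newton iterations on the
latent field (sparse Cholesky solves; the latent vector is
$(\boldsymbol\beta, \tilde\eta, \boldsymbol\phi)$ with a Gaussian prior and
binomial likelihood through the areal observation matrix) inside a
Nelder–Mead search over the four transformed hyperparameters, maximizing the
Laplace-approximated marginal posterior. Hyperparameter uncertainty comes
from a central finite-difference Hessian at the mode (step 0.05); posterior
draws are generated by sampling hyperparameters from that Gaussian
approximation and the latent field from its conditional Gaussian at each
draw. Inner tolerance is $10^{-6}$ relative with step halving; the outer
search runs up to 500 simplex iterations.

`disagg_fit(engine = "mcmc")` is a one-block Metropolis–Hastings sampler:
a random-walk proposal on the hyperparameters (scaled by the Laplace
covariance, Robbins–Monro adapted toward 25% acceptance during warmup)
combined with a latent-field proposal from the conditional Gaussian
approximation at the proposed hyperparameters, accepted jointly. This
targets the exact joint posterior; it reports split-$\widehat R$ and
effective sample sizes and warns above $\widehat R = 1.05$. Defaults are 4
chains of 1000 warmup + 1000 kept iterations. The two engines emit the same
summary schema, and a test requires their posterior-mean grid probabilities
to agree within 0.03 on a three-area toy — this cross-engine agreement is
the package's primary correctness surface for the inference code.

Prediction intervals are equal-tailed quantiles of the sampled cell
probabilities; since the draws are transformed from the logit scale the
intervals are guaranteed to lie in $[0,1]$. Cells outside the partition take
$\phi = 0$ and are flagged. Areas with `observed = FALSE` (e.g. provinces a
survey could not reach) contribute no likelihood but receive full posterior
estimates.

## The simulation study

`run_study()` reproduces the study design on the unit square: a
$60\times60$ prediction grid; $n_A \in \{9, 25, 100\}$ square areas; ranges
$r \in \{0.3, 0.5, 0.7\}$ (i.e. $\kappa \approx 9.4, 5.7, 4.0$); truth
$\boldsymbol\beta = (0.2, 0.4, -0.5, 0.2, -0.2)$, $\sigma_\eta^2 = 1$,
$\rho = 0.6$, $\sigma_\phi^2 = 1$; covariates drawn per cell from $N(0,1)$,
$\mathrm{Gamma}(1,1)$, $\mathrm{Poisson}(5)$ and $t_2$ (used as drawn — the
heavy-tailed $t_2$ is part of the stress test, so no winsorizing); areal
sample sizes $N_i \sim$ discrete $\mathrm{Uniform}(50, 300)$. Area-level
truth uses the block-averaged covariates and the exact grid-cell average of
$\eta$; the fitted model approximates the latter with the mesh vertex rule.
Scoring uses RMSE, Pearson correlation and the empirical coverage of 95%
prediction intervals at both supports, averaged over replicates with
Monte-Carlo standard errors (the coverage indicator evaluates the *true*
probability against the interval). Replicate seeds derive deterministically
from the study seed, and the covariate/GP standard-normal streams coincide
across settings with equal grid sizes — common random numbers that stabilize
cross-setting comparisons at reduced replicate counts. The package default
is 25 replicates per setting (a full-scale evaluation uses 500); the reduced
count is enough for the trend and floor checks the tests make, with SEs
reported alongside.

### What the generator does and does not emulate

The generator reproduces the stated study conditions exactly, but iid
per-cell covariates are a deliberately hard case for change-of-support
regression, and passing tests here does not imply comparable accuracy on
real rasters: real covariates (travel time, population density) are
spatially smooth, which *increases* the areal-level covariate signal and
makes $\boldsymbol\beta$ easier to identify than in this design.

### Identifiability at small $n_A$ — an honest caveat

With $n_A = 9$ areas, block averaging over ~400 cells shrinks the areal
covariate variation to about $1/20$ of its grid-level spread, so the nine
binomial observations carry almost no information about the five
coefficients. Under the vague $N(0, 10^5)$ coefficient prior the posterior
then interpolates the nine area logits through the covariate subspace
(coefficient magnitudes of order 10), and the grid-level predictor — where
covariates have full variance — degrades sharply. This is a property of the
exact posterior, not of an engine: the MCMC and Laplace engines agree on it.
Sensitivity runs included in the package's development history show that
either (a) drawing areal covariates at unit level
(`simulate_dataset(covariate_support = "unit")`), or (b) an informative
coefficient prior (variance near 1), restores sensible behaviour at small
$n_A$; with the conditions exactly as stated, grid-level correlation in the
$r = 0.3$, $n_A = 9$ setting is far below what is attainable at
$n_A = 100$. The package keeps the stated conditions as defaults and
reports what they produce; interval coverage remains calibrated
(approximately 90–97%) throughout, because the posterior is honestly
uncertain precisely where it cannot identify the coefficients.

## Post-processing

`aggregate_to_units()` averages cell predictions within reporting units
(optionally population-weighted); `coldspot_classes()` classifies cells by
the 20/50/80% quantiles of predicted coverage (type-7 quantiles, ties
inclusive downward — the convention is a package choice since only cutpoint
values, not a rule, are conventional); `threshold_attainment()` flags units
reaching a coverage target, read inclusively (≥ 80% attains an 80% target);
`unvaccinated_counts()` integrates $\sum_i \mathrm{pop}_i (1 - \hat p_i)$
with an aligned population raster at cell, unit or national level, recording
in metadata when coverage of 12–23-month-olds is used as a proxy for an
under-5 population.

## Numerical choices

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before logs.
* Dense Matérn factorization uses a jitter ladder
  ($10^{-10} \dots 10^{-6}$ of $\sigma_\eta^2$) on near-singular
  covariances.
* The Leroux log-determinant uses the eigenvalues of the graph Laplacian
  (computed once per adjacency): $\log\det Q(\rho) = \sum_j \log(\rho\mu_j +
  1 - \rho)$, positive for $\rho < 1$.
* Membership ties on shared polygon edges go to the lowest area index
  (deterministic and order-independent); cells outside every polygon are
  flagged, not dropped silently.
* The median pairwise distance is exact up to 2000 points and a seeded
  2000-point subsample above.
* Coordinates are planar throughout; `degrees_to_km()` (1° ≈ 111.32 km) is a
  presentation utility only.

## Problem sizes used by the shipped checks

The package's own test suite runs the study settings on a 30×30 grid with
25 replicates for the floor checks and 6 replicates (with common random
numbers) for the trend checks; the acceptance script uses the full 60×60
grid with 25 replicates per setting. These sizes were chosen so a complete
desk run finishes in minutes while keeping Monte-Carlo SEs small relative to
the margins being checked.

## Known limitations

* No spatially varying coefficients, no anisotropy, $\nu$ fixed at 1.
* No fusion of areal and cluster likelihoods (the cluster-to-grid variant is
  provided as a separate log-posterior).
* Boundary files must share one planar coordinate system; there is no
  reprojection or polygon repair. Shapefile reading is not provided — use
  GeoJSON or supply polygons directly.
* The Laplace engine's hyperparameter uncertainty is Gaussian on the
  transformed scale; heavy-tailed hyperparameter posteriors (tiny data) are
  better served by the MCMC engine.
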