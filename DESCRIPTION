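Package: disaggmap
Title: Disaggregation of Areal Binomial Data to High-Resolution Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint spatial regression model for area-to-point disaggregation
    of binomial outcomes such as vaccination coverage. Areal counts are linked
    to a high-resolution prediction grid through shared regression
    coefficients, a Matern (nu = 1) Gaussian process represented as an
    SPDE-type Gauss-Markov random field on a triangulation, and a Leroux
    conditional autoregressive field on the areal units. Bayesian inference is
    provided by an inner-outer Laplace approximation and by a one-block
    Metropolis-Hastings sampler, together with a simulation study harness and
    map post-processing utilities (district aggregation, coldspot
    classification, coverage-target attainment, unvaccinated-count
    integration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
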