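#' @importFrom stats dnorm dgamma rnorm rgamma rpois rt rbinom runif quantile
#'   median optim plogis qlogis qnorm sd var cor dist acf dbinom setNames
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

invlogit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

## probabilities are clipped before taking logs; numeric safety only
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## z' Q z for base vectors with (possibly sparse) Q
quad_form <- function(z, Q) sum(z * as.numeric(Q %*% z))

#' Survey coverage percentage
#'
#' Computes the percentage of sampled children vaccinated, the summary
#' statistic reported alongside weighted areal survey counts.
#'
#' @param vaccinated number vaccinated (weighted count).
#' @param total number of children surveyed (weighted count).
#' @return Percentage on the 0-100 scale.
#' @examples
#' coverage_percent(3443, 5704)
#' @export
coverage_percent <- function(vaccinated, total) {
  if (any(total <= 0)) stopf("'total' must be positive")
  if (any(vaccinated < 0 | vaccinated > total))
    stopf("'vaccinated' must lie in [0, total]")
  100 * vaccinated / total
}
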