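#' Cost models for the non-monetary burden of adherence
#'
#' The burden of following a prophylactic therapy (time, side effects,
#' emotional distress) is heterogeneous across individuals and is modelled as
#' a non-negative random cost type \eqn{c} with CDF \eqn{F} and density
#' \eqn{f}. A cost model is any S3 object inheriting from class
#' \code{"cost_model"} that implements the four generics
#' \code{\link{cost_cdf}}, \code{\link{cost_pdf}},
#' \code{\link{cost_partial_mean}} and \code{\link{cost_sample}} (plus
#' \code{\link{cost_support_upper}}). Default methods for
#' \code{cost_partial_mean} and \code{cost_support_upper} are provided via
#' adaptive quadrature and CDF inversion, so a concrete model only has to
#' supply its CDF, density and sampler.
#'
#' @name cost_model
NULL

#' Test whether an object is a cost model
#'
#' @param x object to test
#' @return \code{TRUE} if \code{x} inherits from \code{"cost_model"}.
#' @export
is_cost_model <- function(x) inherits(x, "cost_model")

#' Cumulative distribution function of a cost model
#'
#' @param model a \code{\link{cost_model}}
#' @param q vector of cost values
#' @return \eqn{P(c \le q)}, non-decreasing, 0 below the support and 1 above.
#' @export
cost_cdf <- function(model, q) UseMethod("cost_cdf")

#' Density function of a cost model
#'
#' @inheritParams cost_cdf
#' @param x vector of cost values
#' @return density \eqn{f(x) \ge 0}, zero outside the support.
#' @export
cost_pdf <- function(model, x) UseMethod("cost_pdf")

#' Partial mean of a cost model
#'
#' Computes \eqn{\int_a^b c f(c)\,dc}, the mean of \eqn{c} restricted to
#' \eqn{[a, b]} weighted by the probability mass of that interval. This is
#' the integral appearing in the individual-welfare expression.
#'
#' @inheritParams cost_cdf
#' @param lower,upper integration bounds, \code{0 <= lower <= upper}
#' @return a non-negative scalar.
#' @export
cost_partial_mean <- function(model, lower, upper) UseMethod("cost_partial_mean")

#' Draw cost types from a cost model
#'
#' Uses the current R random-number stream; callers that need
#' reproducibility set the seed (as the simulator does with per-purpose
#' child streams).
#'
#' @inheritParams cost_cdf
#' @param n number of draws
#' @return \code{n} non-negative draws from the support.
#' @export
cost_sample <- function(model, n) UseMethod("cost_sample")

#' Effective upper bound of a cost model's support
#'
#' @inheritParams cost_cdf
#' @return the smallest \code{u} with \code{cost_cdf(model, u) >= 1 - 1e-12}
#'   (exact for bounded supports).
#' @export
cost_support_upper <- function(model) UseMethod("cost_support_upper")

#' @export
cost_partial_mean.cost_model <- function(model, lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower >= 0, upper >= lower)
  hi <- min(upper, cost_support_upper(model))
  lo <- min(lower, hi)
  if (hi <= lo) return(0)
  stats::integrate(function(c) c * cost_pdf(model, c), lo, hi,
                   abs.tol = 1e-10, rel.tol = 1e-10)$value
}

#' @export
cost_support_upper.cost_model <- function(model) {
  # doubling search then root refinement on the CDF tail
  hi <- 1
  while (cost_cdf(model, hi) < 1 - 1e-12 && hi < 1e12) hi <- hi * 2
  if (cost_cdf(model, 0) >= 1 - 1e-12) return(0)
  stats::uniroot(function(u) cost_cdf(model, u) - (1 - 1e-12), c(0, hi),
                 tol = 1e-12)$root
}

#' Uniform cost model on [0, c_max]
#'
#' The reference cost distribution: \eqn{f(c) = 1/c_{max}} on
#' \eqn{[0, c_{max}]}, \eqn{F(c) = c/c_{max}}. All welfare quantities have
#' closed forms under this model; the package's generic routines reproduce
#' them exactly because the partial mean \eqn{x^2/(2 c_{max})} is implemented
#' analytically.
#'
#' @param c_max upper bound of the cost support, > 0
#' @return an object of class \code{c("uniform_cost_model", "cost_model")}.
#' @examples
#' m <- uniform_cost_model(0.5)
#' cost_cdf(m, 0.216)          # 0.432
#' cost_partial_mean(m, 0, 0.216)  # 0.216^2 / (2 * 0.5)
#' @export
uniform_cost_model <- function(c_max) {
  stopifnot(is.numeric(c_max), length(c_max) == 1, is.finite(c_max))
  if (c_max <= 0) stop("`c_max` must be > 0", call. = FALSE)
  structure(list(c_max = c_max),
            class = c("uniform_cost_model", "cost_model"))
}

#' @export
cost_cdf.uniform_cost_model <- function(model, q) {
  pmin(pmax(q / model$c_max, 0), 1)
}

#' @export
cost_pdf.uniform_cost_model <- function(model, x) {
  ifelse(x >= 0 & x <= model$c_max, 1 / model$c_max, 0)
}

#' @export
cost_partial_mean.uniform_cost_model <- function(model, lower, upper) {
  stopifnot(lower >= 0, upper >= lower)
  a <- min(max(lower, 0), model$c_max)
  b <- min(max(upper, 0), model$c_max)
  (b^2 - a^2) / (2 * model$c_max)
}

#' @export
cost_sample.uniform_cost_model <- function(model, n) {
  stats::runif(n, 0, model$c_max)
}

#' @export
cost_support_upper.uniform_cost_model <- function(model) model$c_max

#' @export
print.uniform_cost_model <- function(x, ...) {
  cat("Uniform cost model on [0,", format(x$c_max), "]\n")
  invisible(x)
}

#' Scaled Beta cost model on [0, scale]
#'
#' A smooth, non-uniform alternative cost distribution:
#' \eqn{c = scale \cdot X} with \eqn{X \sim Beta(shape1, shape2)}. Its
#' partial mean has no simple closed form and is evaluated by the default
#' quadrature method, which makes it a convenient stress test for the
#' generic cost-model contract.
#'
#' @param shape1,shape2 Beta shape parameters, > 0
#' @param scale upper bound of the support, > 0
#' @return an object of class \code{c("beta_cost_model", "cost_model")}.
#' @export
beta_cost_model <- function(shape1, shape2, scale = 1) {
  stopifnot(shape1 > 0, shape2 > 0, scale > 0)
  structure(list(shape1 = shape1, shape2 = shape2, scale = scale),
            class = c("beta_cost_model", "cost_model"))
}

#' @export
cost_cdf.beta_cost_model <- function(model, q) {
  stats::pbeta(pmin(pmax(q / model$scale, 0), 1), model$shape1, model$shape2)
}

#' @export
cost_pdf.beta_cost_model <- function(model, x) {
  ifelse(x >= 0 & x <= model$scale,
         stats::dbeta(x / model$scale, model$shape1, model$shape2) / model$scale,
         0)
}

#' @export
cost_sample.beta_cost_model <- function(model, n) {
  model$scale * stats::rbeta(n, model$shape1, model$shape2)
}

#' @export
cost_support_upper.beta_cost_model <- function(model) model$scale
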