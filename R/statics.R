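#' Marginal effect of the bonus on adherence
#'
#' The analytic derivative of the adherence probability with respect to the
#' bonus, \eqn{dF/db = f(\beta\delta\Delta p\Delta u + p_D b)\,p_D}: a bonus
#' raises adherence through the density of cost types at the decision
#' threshold, scaled by the probability that abuse is detected. Only defined
#' where the threshold is differentiable; at the edges of the cost support
#' the CDF has a kink and the function signals an error.
#'
#' @param scenario a \code{\link{scenario}}
#' @param boundary_tol how close (absolutely) the threshold may come to a
#'   support boundary before the derivative is declared undefined
#' @return the derivative \eqn{dF/db \ge 0}.
#' @export
marginal_adherence_wrt_bonus <- function(scenario, boundary_tol = 1e-9) {
  stopifnot(inherits(scenario, "scenario"))
  theta <- adherence_threshold(scenario, perspective = 1)
  upper <- cost_support_upper(scenario$cost_model)
  if (abs(theta) <= boundary_tol || abs(theta - upper) <= boundary_tol)
    stop("adherence threshold lies on a cost-support boundary; ",
         "dF/db is not differentiable there", call. = FALSE)
  cost_pdf(scenario$cost_model, theta) * scenario$incentive$detection_prob
}

#' Marginal effect of present bias on societal welfare
#'
#' The analytic derivative of societal welfare with respect to the
#' present-bias weight in the incentive-free model:
#' \deqn{\partial W^S/\partial\beta = -f(\beta\delta\Delta p\Delta u)\,
#'   \delta\Delta p\Delta u\,(C_A - C_{NA} - \Delta p\,\delta C_F).}
#' It is positive exactly when the averted follow-up costs outweigh the
#' extra treatment expenses (\eqn{C_A - C_{NA} < \Delta p\,\delta C_F}) and
#' the cost density at the threshold is positive: then more self-control
#' (higher \eqn{\beta}) benefits society.
#'
#' @param scenario a \code{\link{scenario}} with \code{bonus == 0}
#' @return the derivative \eqn{\partial W^S / \partial \beta}.
#' @export
societal_welfare_beta_derivative <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  if (scenario$incentive$bonus != 0)
    stop("the printed derivative applies to the incentive-free model; ",
         "set bonus = 0", call. = FALSE)
  p <- scenario$preferences
  dpdu <- delta_p(scenario) * delta_u(scenario)
  theta <- p$beta * p$delta * dpdu
  sc <- scenario$societal
  k <- sc$cost_adherent - sc$cost_nonadherent -
    delta_p(scenario) * p$delta * sc$followup_cost
  -cost_pdf(scenario$cost_model, theta) * p$delta * dpdu * k
}

sweep_parameters <- c("beta", "delta", "bonus", "detection_prob",
                      "admin_share", "c_max", "followup_cost")

#' Parameter sweep of adherence and welfare
#'
#' Evaluates adherence probabilities (both perspectives), the self-control
#' gap and the three welfare quantities along a grid of one scenario
#' parameter. Grid points that violate a scenario invariant are skipped with
#' a warning rather than aborting the sweep. Monotonicity flags
#' (non-decreasing / non-increasing per output column over the evaluated
#' grid) are attached as the \code{"monotonicity"} attribute.
#'
#' @param scenario the baseline \code{\link{scenario}}
#' @param parameter one of \code{"beta"}, \code{"delta"}, \code{"bonus"},
#'   \code{"detection_prob"}, \code{"admin_share"}, \code{"c_max"} (uniform
#'   cost model only), \code{"followup_cost"}
#' @param grid strictly increasing numeric grid of parameter values
#' @return a data frame of class \code{"sweep_table"} with columns
#'   \code{parameter}, \code{value}, \code{adherence_planned} (t = 0
#'   perspective), \code{adherence_actual} (t = 1), \code{self_control_gap},
#'   \code{individual}, \code{societal}, \code{total}.
#' @export
parameter_sweep <- function(scenario, parameter, grid) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% sweep_parameters)
    stop("unknown sweep parameter `", parameter, "`; must be one of: ",
         paste(sweep_parameters, collapse = ", "), call. = FALSE)
  if (!is.numeric(grid) || length(grid) < 1 ||
      (length(grid) > 1 && any(diff(grid) <= 0)))
    stop("`grid` must be a strictly increasing numeric vector", call. = FALSE)

  rows <- lapply(grid, function(v) {
    s <- tryCatch(do.call(update_scenario, stats::setNames(
      list(scenario, v), c("scenario", parameter))),
      error = function(e) {
        warning("skipping ", parameter, " = ", v, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(s)) return(NULL)
    data.frame(parameter = parameter, value = v,
               adherence_planned = adherence_probability(s, perspective = 0),
               adherence_actual = adherence_probability(s, perspective = 1),
               self_control_gap = self_control_gap(s),
               individual = individual_welfare(s),
               societal = societal_welfare(s),
               total = total_welfare(s))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no valid grid points in the sweep", call. = FALSE)
  class(tab) <- c("sweep_table", "data.frame")
  num_cols <- setdiff(names(tab), c("parameter", "value"))
  attr(tab, "monotonicity") <- lapply(
    stats::setNames(num_cols, num_cols),
    function(cl) {
      d <- diff(tab[[cl]])
      c(non_decreasing = all(d >= -1e-12), non_increasing = all(d <= 1e-12))
    })
  tab
}
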