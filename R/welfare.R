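#' Expected cost type among adherent individuals
#'
#' The mean cost borne by those who actually adhere, i.e. the mean of the
#' cost distribution truncated to \eqn{[0, \theta]} with
#' \eqn{\theta = \beta\delta\Delta p\Delta u + p_D b}:
#' \eqn{E^A[c] = \frac{1}{F(\theta)} \int_0^\theta c f(c)\,dc}. When nobody
#' adheres (\eqn{F(\theta) = 0}) the value is 0 by convention.
#'
#' @param scenario a \code{\link{scenario}}
#' @return expected cost (money scale), >= 0.
#' @export
expected_cost_given_adherent <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  theta <- adherence_threshold(scenario, perspective = 1)
  f_adh <- adherence_probability(scenario, perspective = 1)
  if (f_adh <= 0 || theta <= 0) return(0)
  cost_partial_mean(scenario$cost_model, 0, theta) / f_adh
}

#' Individual welfare of the treatment contract
#'
#' Expected net utility of accepting the treatment contract relative to
#' rejecting it, from the acting (t = 1) perspective:
#' \deqn{W^I = -\int_0^\theta c f(c)\,dc + F(\theta)\,\theta + (1 - p_D) b}
#' with \eqn{\theta = \beta\delta\Delta p\Delta u + p_D b}. The last term is
#' the bonus improperly collected by undetected non-adherents. Under the
#' uniform cost model this reproduces the piecewise closed form
#' \eqn{\theta^2 / (2 c_{max}) + (1 - p_D) b} below full adherence and
#' \eqn{-c_{max}/2 + \beta\delta\Delta p\Delta u + b} at or above it; for
#' other cost models the integral is evaluated by adaptive quadrature.
#'
#' @param scenario a \code{\link{scenario}}
#' @return individual welfare (shared money-utility scale).
#' @export
individual_welfare <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  theta <- adherence_threshold(scenario, perspective = 1)
  f_adh <- adherence_probability(scenario, perspective = 1)
  b <- scenario$incentive$bonus
  p_d <- scenario$incentive$detection_prob
  pm <- if (theta > 0) cost_partial_mean(scenario$cost_model, 0, theta) else 0
  -pm + f_adh * theta + (1 - p_d) * b
}

#' Societal welfare of the treatment contract
#'
#' The monetary component of welfare borne by society: prophylaxis expenses
#' at t = 1, savings on follow-up costs of illness averted at t = 2
#' (discounted by \eqn{\delta} only — society applies no present bias), and
#' the bonus payout including its administrative overhead \eqn{\lambda}:
#' \deqn{W^S = -C_{NA} - F\,(C_A - C_{NA} - \Delta p\,\delta C_F)
#'   - [F + (1 - F)(1 - p_D)]\,(1 + \lambda)\,b}
#' with \eqn{F = F(\beta\delta\Delta p\Delta u + p_D b)}. At \eqn{b = 0} this
#' reduces exactly to the incentive-free expression.
#'
#' @param scenario a \code{\link{scenario}}
#' @return societal welfare (money scale).
#' @export
societal_welfare <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  f_adh <- adherence_probability(scenario, perspective = 1)
  sc <- scenario$societal
  inc <- scenario$incentive
  net_cost <- sc$cost_adherent - sc$cost_nonadherent -
    delta_p(scenario) * scenario$preferences$delta * sc$followup_cost
  payout_share <- f_adh + (1 - f_adh) * (1 - inc$detection_prob)
  -sc$cost_nonadherent - f_adh * net_cost -
    payout_share * (1 + inc$admin_share) * inc$bonus
}

#' Total welfare
#'
#' The joint welfare \eqn{W = W^I + W^S}. With \eqn{\lambda = 0} the bonus
#' itself is a pure redistribution between individuals and society; only the
#' induced change in adherence and the administrative overhead move \eqn{W}.
#'
#' @param scenario a \code{\link{scenario}}
#' @return total welfare (shared money-utility scale).
#' @seealso \code{\link{total_welfare_closed_form}} for the uniform-cost
#'   quadratic-in-bonus expression used as a cross-check.
#' @export
total_welfare <- function(scenario) {
  individual_welfare(scenario) + societal_welfare(scenario)
}

#' Closed-form total welfare under uniform costs and full observability
#'
#' The quadratic-in-bonus expression for total welfare valid under a uniform
#' cost model, complete observability (\eqn{p_D = 1}) and incomplete
#' adherence (\eqn{\beta\delta\Delta p\Delta u + b < c_{max}}):
#' \deqn{W = \frac{1}{2 c_{max}}\left[A^2 - 2AK - 2(K + A\lambda)b
#'   - (1 + 2\lambda)b^2\right] - C_{NA}}
#' with \eqn{A = \beta\delta\Delta p\Delta u} and
#' \eqn{K = C_A - C_{NA} - \Delta p\,\delta C_F}. It is algebraically equal
#' to \code{\link{total_welfare}} on its validity domain and serves as an
#' independent oracle for it.
#'
#' @param scenario a \code{\link{scenario}} with a uniform cost model,
#'   \code{detection_prob == 1} and an interior threshold
#' @return total welfare (shared money-utility scale).
#' @export
total_welfare_closed_form <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  if (!inherits(scenario$cost_model, "uniform_cost_model"))
    stop("closed form requires a uniform cost model", call. = FALSE)
  if (scenario$incentive$detection_prob != 1)
    stop("closed form requires detection_prob = 1 (complete observability)",
         call. = FALSE)
  a <- scenario$preferences$beta * scenario$preferences$delta *
    delta_p(scenario) * delta_u(scenario)
  b <- scenario$incentive$bonus
  c_max <- scenario$cost_model$c_max
  if (a + b >= c_max)
    stop("closed form requires incomplete adherence ",
         "(beta*delta*delta_p*delta_u + b < c_max)", call. = FALSE)
  lambda <- scenario$incentive$admin_share
  sc <- scenario$societal
  k <- sc$cost_adherent - sc$cost_nonadherent -
    delta_p(scenario) * scenario$preferences$delta * sc$followup_cost
  (a^2 - 2 * a * k - 2 * (k + a * lambda) * b - (1 + 2 * lambda) * b^2) /
    (2 * c_max) - sc$cost_nonadherent
}

#' Is a welfare-improving bonus feasible?
#'
#' A positive bonus can raise total welfare only if the administrative
#' overhead is not too high:
#' \eqn{\lambda < (\delta\Delta p C_F - (C_A - C_{NA})) /
#' (\beta\delta\Delta p\Delta u)} (strict inequality). When the denominator
#' is zero (e.g. \eqn{\beta = 0}) the condition is reported as the sign of
#' the numerator.
#'
#' @param scenario a \code{\link{scenario}}
#' @return \code{TRUE} if the feasibility condition holds.
#' @export
bonus_feasibility <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sc <- scenario$societal
  num <- scenario$preferences$delta * delta_p(scenario) * sc$followup_cost -
    (sc$cost_adherent - sc$cost_nonadherent)
  den <- scenario$preferences$beta * scenario$preferences$delta *
    delta_p(scenario) * delta_u(scenario)
  if (den == 0) return(num > 0)
  scenario$incentive$admin_share < num / den
}

#' Welfare-maximizing bonus
#'
#' Finds the bonus \eqn{b^*} maximizing total welfare. Under complete
#' observability (\eqn{p_D = 1}), uniform costs and an interior solution the
#' first-order condition gives the closed form
#' \deqn{b^* = \frac{\delta\Delta p C_F - (C_A - C_{NA})
#'   - \beta\delta\Delta p\Delta u\,\lambda}{1 + 2\lambda}.}
#' Outside that domain (partial observability, non-uniform costs, boundary
#' solutions) a coarse grid search over \eqn{[0, b_{upper}]} followed by
#' golden-section refinement is used; by default \eqn{b_{upper}} is the bonus
#' that already guarantees full adherence plus one support width, beyond
#' which welfare cannot increase. If the feasibility condition
#' (\code{\link{bonus_feasibility}}) fails, a warning is issued and the
#' (typically zero) constrained maximizer is still reported with
#' \code{feasible = FALSE}.
#'
#' @param scenario a \code{\link{scenario}}
#' @param method \code{"auto"} (closed form where valid, else numeric),
#'   \code{"closed_form"} or \code{"numeric"}
#' @param b_upper upper bound of the numeric search; default described above
#' @param grid_points number of points of the coarse grid
#' @return a list of class \code{"bonus_solution"} with elements
#'   \code{b_star}, \code{welfare} (total welfare at \code{b_star}),
#'   \code{feasible}, \code{interior} and \code{method}.
#' @export
optimal_bonus <- function(scenario,
                          method = c("auto", "closed_form", "numeric"),
                          b_upper = NULL, grid_points = 10000) {
  stopifnot(inherits(scenario, "scenario"))
  method <- match.arg(method)
  p <- scenario$preferences
  sc <- scenario$societal
  a <- p$beta * p$delta * delta_p(scenario) * delta_u(scenario)
  upper_support <- cost_support_upper(scenario$cost_model)
  feasible <- bonus_feasibility(scenario)
  if (!feasible)
    warning("administrative overhead too high: a bonus cannot raise total ",
            "welfare (lambda feasibility condition fails)", call. = FALSE)

  lambda <- scenario$incentive$admin_share
  b_cf <- (p$delta * delta_p(scenario) * sc$followup_cost -
             (sc$cost_adherent - sc$cost_nonadherent) -
             a * lambda) / (1 + 2 * lambda)
  cf_valid <- scenario$incentive$detection_prob == 1 &&
    inherits(scenario$cost_model, "uniform_cost_model") &&
    b_cf >= 0 && a + b_cf < upper_support

  if (method == "closed_form") {
    if (!cf_valid)
      stop("closed form not applicable: requires p_D = 1, uniform costs and ",
           "an interior non-negative solution", call. = FALSE)
    w <- total_welfare(update_scenario(scenario, bonus = b_cf))
    return(structure(list(b_star = b_cf, welfare = w, feasible = feasible,
                          interior = TRUE, method = "closed_form"),
                     class = "bonus_solution"))
  }
  if (method == "auto" && cf_valid && feasible) {
    w <- total_welfare(update_scenario(scenario, bonus = b_cf))
    return(structure(list(b_star = b_cf, welfare = w, feasible = feasible,
                          interior = TRUE, method = "closed_form"),
                     class = "bonus_solution"))
  }

  # numeric search: welfare is flat in b beyond full adherence except for the
  # (weakly negative) payout term, so a finite bracket suffices
  if (is.null(b_upper)) {
    p_d <- scenario$incentive$detection_prob
    b_full <- if (p_d > 0) max((upper_support - a) / p_d, 0) else upper_support
    b_upper <- b_full + upper_support
  }
  # any finite bonus is valid, so mutate it directly instead of re-running
  # the full constructor validation at every grid point
  w_of_b <- function(b) {
    s2 <- scenario
    s2$incentive$bonus <- b
    total_welfare(s2)
  }
  grid <- seq(0, b_upper, length.out = grid_points)
  w_grid <- vapply(grid, w_of_b, numeric(1))
  i <- which.max(w_grid)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(w_of_b, lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-8)
  b_star <- opt$maximum
  w_star <- opt$objective
  # boundary beats the refined interior point when welfare is monotone
  if (w_grid[i] > w_star) { b_star <- grid[i]; w_star <- w_grid[i] }
  if (w_of_b(0) > w_star) { b_star <- 0; w_star <- w_of_b(0) }
  theta_star <- a + scenario$incentive$detection_prob * b_star
  structure(list(b_star = b_star, welfare = w_star, feasible = feasible,
                 interior = theta_star < upper_support && b_star > 0,
                 method = "numeric"),
            class = "bonus_solution")
}

#' @export
print.bonus_solution <- function(x, ...) {
  cat("Welfare-maximizing bonus\n")
  cat(sprintf("  b*        : %.10g\n", x$b_star))
  cat(sprintf("  W(b*)     : %.10g\n", x$welfare))
  cat(sprintf("  feasible  : %s   interior: %s   method: %s\n",
              x$feasible, x$interior, x$method))
  invisible(x)
}

#' Full welfare report for a scenario
#'
#' @param scenario a \code{\link{scenario}}
#' @return a list of class \code{"welfare_report"} with elements
#'   \code{adherence_prob} (acting perspective),
#'   \code{expected_cost_adherent}, \code{individual}, \code{societal} and
#'   \code{total} (always equal to \code{individual + societal}).
#' @export
welfare_report <- function(scenario) {
  ind <- individual_welfare(scenario)
  soc <- societal_welfare(scenario)
  structure(list(
    adherence_prob = adherence_probability(scenario, perspective = 1),
    expected_cost_adherent = expected_cost_given_adherent(scenario),
    individual = ind,
    societal = soc,
    total = ind + soc
  ), class = "welfare_report")
}

#' @export
print.welfare_report <- function(x, ...) {
  cat("Welfare report\n")
  cat(sprintf("  adherence probability F : %.6g\n", x$adherence_prob))
  cat(sprintf("  E[c | adherent]         : %.6g\n", x$expected_cost_adherent))
  cat(sprintf("  individual welfare W^I  : %.6g\n", x$individual))
  cat(sprintf("  societal welfare  W^S   : %.6g\n", x$societal))
  cat(sprintf("  total welfare     W     : %.6g\n", x$total))
  invisible(x)
}

#' Effect of a co-payment relative to free treatment
#'
#' A co-payment is a negative bonus: adherent patients pay \code{copay} with
#' certainty, non-adherent ones escape it with probability
#' \eqn{1 - p_D}. This function evaluates the scenario at
#' \code{bonus = -copay} and returns the change of each welfare quantity
#' relative to \code{bonus = 0}. Adherence and individual welfare never
#' increase under a co-payment.
#'
#' @param scenario a \code{\link{scenario}}; its bonus is ignored
#' @param copay co-payment amount, >= 0
#' @return a list of class \code{"copayment_report"} with the levels at
#'   \code{b = -copay} (\code{with_copay}), at \code{b = 0}
#'   (\code{baseline}), and the element-wise \code{delta}.
#' @export
copayment_report <- function(scenario, copay) {
  stopifnot(is.numeric(copay), length(copay) == 1, copay >= 0)
  base <- welfare_report(update_scenario(scenario, bonus = 0))
  with_cp <- welfare_report(update_scenario(scenario, bonus = -copay))
  delta <- Map(function(a, b) a - b, unclass(with_cp), unclass(base))
  structure(list(copay = copay, baseline = base, with_copay = with_cp,
                 delta = delta),
            class = "copayment_report")
}

#' @export
print.copayment_report <- function(x, ...) {
  cat(sprintf("Co-payment report (copay = %g)\n", x$copay))
  cat(sprintf("  adherence : %.6g -> %.6g (delta %.6g)\n",
              x$baseline$adherence_prob, x$with_copay$adherence_prob,
              x$delta$adherence_prob))
  cat(sprintf("  W^I       : %.6g -> %.6g (delta %.6g)\n",
              x$baseline$individual, x$with_copay$individual,
              x$delta$individual))
  cat(sprintf("  W^S       : %.6g -> %.6g (delta %.6g)\n",
              x$baseline$societal, x$with_copay$societal, x$delta$societal))
  cat(sprintf("  W         : %.6g -> %.6g (delta %.6g)\n",
              x$baseline$total, x$with_copay$total, x$delta$total))
  invisible(x)
}
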