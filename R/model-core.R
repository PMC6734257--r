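#' Expected period-2 utility
#'
#' The utility the individual expects to experience in period t = 2, i.e.
#' the transition-probability-weighted average of the two health-state
#' utilities: \eqn{p \cdot u_{healthy} + (1 - p) \cdot u_{sick}} with
#' \eqn{p = p_A} under adherence and \eqn{p = p_{NA}} otherwise.
#'
#' @param therapy a \code{\link{therapy}} object
#' @param utilities a \code{\link{health_utilities}} object
#' @param adherent logical; evaluate under adherence?
#' @return the expected period-2 utility (dimensionless).
#' @export
expected_stage2_utility <- function(therapy, utilities, adherent) {
  stopifnot(inherits(therapy, "therapy"),
            inherits(utilities, "health_utilities"),
            is.logical(adherent), length(adherent) == 1, !is.na(adherent))
  p <- if (adherent) therapy$p_adherent else therapy$p_nonadherent
  p * utilities$u_healthy + (1 - p) * utilities$u_sick
}

check_perspective <- function(perspective) {
  if (!(is.numeric(perspective) && length(perspective) == 1 &&
        perspective %in% c(0, 1)))
    stop("`perspective` must be 0 (planning) or 1 (acting)", call. = FALSE)
  perspective
}

#' Intertemporal utility of the t = 1 decision
#'
#' Evaluates the quasi-hyperbolically discounted utility of adhering or not,
#' either from the planning perspective of period t = 0 (all later periods
#' weighted by \eqn{\beta\delta} and \eqn{\beta\delta^2}) or from the acting
#' perspective of period t = 1 (weights 1 and \eqn{\beta\delta}). An adherent
#' individual bears the cost type \code{cost} and receives the bonus \eqn{b};
#' a non-adherent individual collects the bonus undetected with probability
#' \eqn{1 - p_D}, contributing \eqn{(1 - p_D) b} in expectation.
#'
#' @param scenario a \code{\link{scenario}}
#' @param perspective 0 or 1, the period from which the t = 1 choice is
#'   evaluated
#' @param adherent logical; utility of the adherent branch?
#' @param cost the individual's cost type (required, and must be >= 0, when
#'   \code{adherent = TRUE}; ignored otherwise)
#' @return the intertemporal utility (dimensionless).
#' @export
intertemporal_utility <- function(scenario, perspective, adherent, cost = 0) {
  stopifnot(inherits(scenario, "scenario"),
            is.logical(adherent), length(adherent) == 1, !is.na(adherent))
  check_perspective(perspective)
  if (adherent && (!is.numeric(cost) || length(cost) != 1 || cost < 0))
    stop("`cost` must be a single value >= 0 for the adherent branch",
         call. = FALSE)
  beta <- scenario$preferences$beta
  delta <- scenario$preferences$delta
  u_h <- scenario$utilities$u_healthy
  b <- scenario$incentive$bonus
  p_d <- scenario$incentive$detection_prob
  u2 <- expected_stage2_utility(scenario$therapy, scenario$utilities, adherent)
  period1 <- if (adherent) -(cost - b) + u_h else (1 - p_d) * b + u_h
  if (perspective == 1) {
    period1 + beta * delta * u2
  } else {
    beta * delta * period1 + beta * delta^2 * u2
  }
}

#' Cost threshold below which the individual adheres
#'
#' From the planning perspective (t = 0) the individual intends to adhere
#' whenever the cost type satisfies
#' \eqn{c \le \delta \Delta p \Delta u + p_D b}; when the moment of action
#' arrives (t = 1) the present bias shrinks the future benefit and the
#' criterion becomes \eqn{c \le \beta\delta \Delta p \Delta u + p_D b}. The
#' threshold is exactly the cost at which the two intertemporal utilities
#' coincide. It may be negative (a large co-payment) or exceed the cost
#' support (guaranteed adherence).
#'
#' @inheritParams intertemporal_utility
#' @return the cost bound (same scale as the cost type).
#' @export
adherence_threshold <- function(scenario, perspective) {
  stopifnot(inherits(scenario, "scenario"))
  check_perspective(perspective)
  p <- scenario$preferences
  w <- if (perspective == 0) p$delta else p$beta * p$delta
  w * delta_p(scenario) * delta_u(scenario) +
    scenario$incentive$detection_prob * scenario$incentive$bonus
}

#' Population probability of adherence
#'
#' The fraction of the (contract-accepting) population whose cost type falls
#' below the adherence threshold: \eqn{F(\beta\delta\Delta p\Delta u + p_D b)}
#' from the acting perspective, \eqn{F(\delta\Delta p\Delta u + p_D b)} from
#' the planning perspective. Thresholds outside the cost support are clamped
#' through the CDF, so the result is always in [0, 1].
#'
#' @inheritParams intertemporal_utility
#' @return a probability in [0, 1].
#' @export
adherence_probability <- function(scenario, perspective) {
  theta <- adherence_threshold(scenario, perspective)
  min(max(cost_cdf(scenario$cost_model, theta), 0), 1)
}

#' Self-control gap
#'
#' The difference between the adherence probability planned at t = 0 and the
#' probability realised at t = 1,
#' \eqn{F(\delta\Delta p\Delta u + p_D b) - F(\beta\delta\Delta p\Delta u + p_D b)}.
#' It is always non-negative, zero for time-consistent preferences
#' (\eqn{\beta = 1}), and strictly positive when \eqn{\beta < 1} and the cost
#' density is positive between the two thresholds: the behavioural signature
#' of individuals abandoning their own treatment plans.
#'
#' @param scenario a \code{\link{scenario}}
#' @return a probability difference in [0, 1].
#' @export
self_control_gap <- function(scenario) {
  adherence_probability(scenario, perspective = 0) -
    adherence_probability(scenario, perspective = 1)
}

#' Individual adherence decision
#'
#' An individual with cost type \code{cost} adheres if and only if the cost
#' does not exceed the adherence threshold; ties go to adherence (the
#' criterion is a weak inequality).
#'
#' @param cost cost type(s), >= 0 (vectorised)
#' @param scenario a \code{\link{scenario}}
#' @param perspective 0 or 1; the actual decision is taken at t = 1
#' @return logical vector, \code{TRUE} for adherence.
#' @export
decide <- function(cost, scenario, perspective = 1) {
  stopifnot(is.numeric(cost), all(cost >= 0))
  cost <= adherence_threshold(scenario, perspective)
}
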