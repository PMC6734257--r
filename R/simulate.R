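#' Simulate a synthetic population through the three-period model
#'
#' Agent-based Monte Carlo counterpart of the closed-form analysis. Every
#' agent accepts the treatment contract at t = 0 (contract rejection only
#' enters as the welfare baseline), learns a cost type drawn from the
#' scenario's cost model, decides at t = 1 by the acting-perspective
#' threshold rule, and transitions to the t = 2 health state with probability
#' \eqn{p_A} or \eqn{p_{NA}}. When a bonus scheme is active, the abuse of a
#' non-adherent claimant is detected with probability \eqn{p_D}; undetected
#' non-adherents collect the bonus.
#'
#' Per-agent welfare contributions are measured net of the contract-rejection
#' baseline so that their means estimate \eqn{W^I} and \eqn{W^S}. By default
#' the t = 2 health utility and follow-up cost enter as their conditional
#' expectations given the adherence decision (a variance-reduction device;
#' detection outcomes and bonus payouts are always realized draws). With
#' \code{realized = TRUE} the realized t = 2 health state is used instead.
#'
#' Randomness is reproducible: the root \code{seed} spawns independent child
#' streams for costs, health transitions and detection, so switching
#' detection on or off does not perturb the cost draws.
#'
#' @param scenario a \code{\link{scenario}}
#' @param n number of agents, >= 1
#' @param seed integer root seed
#' @param realized logical; use fully realized t = 2 outcomes in the welfare
#'   contributions instead of conditional expectations
#' @return a list of class \code{"simulation_result"} with elements \code{n},
#'   \code{seed}, \code{records} (a data frame with one row per agent:
#'   \code{cost}, \code{adherent}, \code{healthy_t2}, \code{detected},
#'   \code{utility}, \code{societal_cost}), \code{empirical_adherence},
#'   \code{empirical_W_I}, \code{empirical_W_S} and \code{standard_errors}.
#' @examples
#' s <- scenario(preferences(0.8, 0.9), therapy(0.9, 0.6),
#'               health_utilities(1, 0), uniform_cost_model(0.5),
#'               societal = societal_costs(0.05, 0.01, 1))
#' sim <- simulate_population(s, n = 10000, seed = 1)
#' sim$empirical_adherence  # close to 0.432
#' @export
simulate_population <- function(scenario, n, seed, realized = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a positive agent count", call. = FALSE)
  n <- as.integer(n)
  stopifnot(is.numeric(seed), length(seed) == 1)

  # child streams: costs / health / detection
  set.seed(as.integer(seed))
  child <- sample.int(.Machine$integer.max - 1L, 3)

  p <- scenario$preferences
  th <- scenario$therapy
  u <- scenario$utilities
  inc <- scenario$incentive
  sc <- scenario$societal
  bd <- p$beta * p$delta

  set.seed(child[1])
  cost <- cost_sample(scenario$cost_model, n)
  adherent <- decide(cost, scenario, perspective = 1)

  set.seed(child[2])
  p_healthy <- ifelse(adherent, th$p_adherent, th$p_nonadherent)
  healthy_t2 <- stats::runif(n) < p_healthy

  set.seed(child[3])
  det_u <- stats::runif(n)
  detected <- !adherent & inc$bonus != 0 & det_u < inc$detection_prob

  # bonus actually received: adherents always, non-adherents only undetected
  payout <- ifelse(adherent, inc$bonus,
                   ifelse(detected, 0, ifelse(inc$bonus != 0, inc$bonus, 0)))

  # individual utility net of the contract-rejection baseline U1_NA (b = 0):
  # the period-1 health utility cancels, the t = 2 term contributes through
  # the difference to the non-adherent transition probabilities
  u2_na_exp <- expected_stage2_utility(th, u, adherent = FALSE)
  if (realized) {
    u2 <- ifelse(healthy_t2, u$u_healthy, u$u_sick)
    t2_term <- bd * (u2 - u2_na_exp)
  } else {
    u2_exp <- p_healthy * u$u_healthy + (1 - p_healthy) * u$u_sick
    t2_term <- bd * (u2_exp - u2_na_exp)
  }
  utility <- ifelse(adherent, -cost, 0) + payout + t2_term

  # societal contribution net of the rejection baseline -(1 - p_NA) delta C_F
  treat_cost <- ifelse(adherent, sc$cost_adherent, sc$cost_nonadherent)
  if (realized) {
    followup <- ifelse(healthy_t2, 0, p$delta * sc$followup_cost)
  } else {
    followup <- (1 - p_healthy) * p$delta * sc$followup_cost
  }
  baseline_followup <- (1 - th$p_nonadherent) * p$delta * sc$followup_cost
  societal <- -treat_cost - followup + baseline_followup -
    (1 + inc$admin_share) * payout

  records <- data.frame(cost = cost, adherent = adherent,
                        healthy_t2 = healthy_t2, detected = detected,
                        utility = utility, societal_cost = societal)
  se <- function(x) stats::sd(x) / sqrt(n)
  structure(list(
    n = n, seed = seed, realized = realized, records = records,
    empirical_adherence = mean(adherent),
    empirical_W_I = mean(utility),
    empirical_W_S = mean(societal),
    standard_errors = c(adherence = se(adherent), W_I = se(utility),
                        W_S = se(societal))
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monte Carlo simulation: %d agents (seed %g%s)\n", x$n, x$seed,
              if (x$realized) ", realized outcomes" else ""))
  cat(sprintf("  adherence : %.5f (se %.2e)\n", x$empirical_adherence,
              x$standard_errors["adherence"]))
  cat(sprintf("  W^I       : %.5f (se %.2e)\n", x$empirical_W_I,
              x$standard_errors["W_I"]))
  cat(sprintf("  W^S       : %.5f (se %.2e)\n", x$empirical_W_S,
              x$standard_errors["W_S"]))
  invisible(x)
}

#' Compare Monte Carlo estimates with the closed forms
#'
#' Simulates a population and contrasts the empirical adherence probability,
#' individual welfare and societal welfare with their analytic values,
#' reporting a z-score per quantity and a pass flag at |z| <= 3.
#'
#' @inheritParams simulate_population
#' @param n number of agents, >= 1000
#' @return a data frame of class \code{"mc_comparison"} with columns
#'   \code{quantity}, \code{analytic}, \code{estimate}, \code{se}, \code{z}
#'   and \code{pass}.
#' @export
mc_vs_analytic <- function(scenario, n, seed, realized = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1000)
    stop("`n` must be at least 1000 for a meaningful comparison",
         call. = FALSE)
  sim <- simulate_population(scenario, n, seed, realized = realized)
  analytic <- c(adherence = adherence_probability(scenario, perspective = 1),
                W_I = individual_welfare(scenario),
                W_S = societal_welfare(scenario))
  estimate <- c(adherence = sim$empirical_adherence,
                W_I = sim$empirical_W_I,
                W_S = sim$empirical_W_S)
  se <- sim$standard_errors
  z <- ifelse(se > 0, (estimate - analytic) / se,
              ifelse(abs(estimate - analytic) < 1e-12, 0, Inf))
  out <- data.frame(quantity = names(analytic), analytic = analytic,
                    estimate = estimate, se = as.numeric(se),
                    z = as.numeric(z), pass = abs(z) <= 3,
                    row.names = NULL)
  class(out) <- c("mc_comparison", "data.frame")
  attr(out, "n") <- sim$n
  attr(out, "seed") <- seed
  out
}
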