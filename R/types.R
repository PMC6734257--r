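#' Time preferences: present bias and exponential discounting
#'
#' Quasi-hyperbolic discounting assigns weight 1 to the current period and
#' weights \eqn{\beta\delta, \beta\delta^2, \ldots} to the following ones.
#' \eqn{\beta = 1} recovers standard exponential discounting (time-consistent
#' behaviour); \eqn{\beta < 1} produces a present bias. \eqn{\beta = 0} is
#' admitted as a limiting value for welfare analysis.
#'
#' @param beta present-bias weight, in [0, 1]
#' @param delta exponential discount factor, in (0, 1]
#' @return an object of class \code{"preferences"}.
#' @export
preferences <- function(beta, delta) {
  stopifnot(is.numeric(beta), length(beta) == 1,
            is.numeric(delta), length(delta) == 1)
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("`beta` must lie in [0, 1] (present-bias weight)", call. = FALSE)
  if (!is.finite(delta) || delta <= 0 || delta > 1)
    stop("`delta` must lie in (0, 1] (discount factor)", call. = FALSE)
  structure(list(beta = beta, delta = delta), class = "preferences")
}

#' Prophylactic therapy effectiveness
#'
#' Transition probabilities of remaining healthy at t = 2: \code{p_adherent}
#' under adherence and \code{p_nonadherent} without it. The effectiveness of
#' the therapy is \eqn{\Delta p = p_A - p_{NA} > 0}.
#'
#' @param p_adherent probability of staying healthy given adherence
#' @param p_nonadherent probability of staying healthy given non-adherence
#' @return an object of class \code{"therapy"}.
#' @export
therapy <- function(p_adherent, p_nonadherent) {
  stopifnot(is.numeric(p_adherent), length(p_adherent) == 1,
            is.numeric(p_nonadherent), length(p_nonadherent) == 1)
  if (p_nonadherent < 0 || p_adherent > 1 || p_nonadherent >= p_adherent)
    stop("need 0 <= p_nonadherent < p_adherent <= 1 (so that delta_p > 0)",
         call. = FALSE)
  structure(list(p_adherent = p_adherent, p_nonadherent = p_nonadherent),
            class = "therapy")
}

#' Health-state utilities
#'
#' The model has exactly two health states, healthy and sick, valued at
#' \code{u_healthy} and \code{u_sick} with
#' \eqn{\Delta u = u_{healthy} - u_{sick} > 0}.
#'
#' @param u_healthy utility of the healthy (asymptomatic) state
#' @param u_sick utility of the sick state
#' @return an object of class \code{"health_utilities"}.
#' @export
health_utilities <- function(u_healthy, u_sick) {
  stopifnot(is.numeric(u_healthy), length(u_healthy) == 1,
            is.numeric(u_sick), length(u_sick) == 1)
  if (!(u_healthy > u_sick))
    stop("need u_healthy > u_sick (so that delta_u > 0)", call. = FALSE)
  structure(list(u_healthy = u_healthy, u_sick = u_sick),
            class = "health_utilities")
}

#' Financial incentive scheme
#'
#' Adherent patients receive a monetary bonus \code{bonus}; a non-adherent
#' patient improperly collects it unless the abuse is detected, which happens
#' with probability \code{detection_prob}. Running the scheme costs society an
#' overhead of \code{admin_share} (a fraction \eqn{\lambda}) of every unit of
#' bonus paid out. A negative bonus represents a co-payment; in that case
#' "detection" means the co-payment is actually enforced on a non-adherent
#' claimant, so a non-adherent still faces the payment \code{bonus} with
#' probability \code{1 - detection_prob}.
#'
#' @param bonus bonus amount (money; may be negative for a co-payment)
#' @param detection_prob probability that bonus abuse is detected, in [0, 1]
#' @param admin_share administrative overhead per unit bonus, >= 0
#' @return an object of class \code{"incentive_scheme"}.
#' @export
incentive_scheme <- function(bonus = 0, detection_prob = 1, admin_share = 0) {
  stopifnot(is.numeric(bonus), length(bonus) == 1, is.finite(bonus),
            is.numeric(detection_prob), length(detection_prob) == 1,
            is.numeric(admin_share), length(admin_share) == 1)
  if (detection_prob < 0 || detection_prob > 1)
    stop("`detection_prob` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(admin_share) || admin_share < 0)
    stop("`admin_share` must be >= 0", call. = FALSE)
  structure(list(bonus = bonus, detection_prob = detection_prob,
                 admin_share = admin_share),
            class = "incentive_scheme")
}

#' Societal cost parameters
#'
#' Prophylaxis expenses borne by society in period t = 1 (\code{cost_adherent}
#' for adherent, \code{cost_nonadherent} for non-adherent individuals, with
#' \eqn{C_{NA} < C_A}) and the follow-up cost \code{followup_cost} of an
#' individual falling ill in period t = 2 (medical plus productivity losses).
#'
#' @param cost_adherent treatment cost for an adherent individual, >= 0
#' @param cost_nonadherent treatment cost for a non-adherent individual, >= 0
#' @param followup_cost cost of illness in period t = 2, >= 0
#' @return an object of class \code{"societal_costs"}.
#' @export
societal_costs <- function(cost_adherent, cost_nonadherent, followup_cost) {
  stopifnot(is.numeric(cost_adherent), length(cost_adherent) == 1,
            is.numeric(cost_nonadherent), length(cost_nonadherent) == 1,
            is.numeric(followup_cost), length(followup_cost) == 1)
  if (cost_adherent < 0 || cost_nonadherent < 0 || followup_cost < 0)
    stop("societal costs must be >= 0", call. = FALSE)
  if (!(cost_nonadherent < cost_adherent))
    stop("need cost_nonadherent < cost_adherent (C_NA < C_A)", call. = FALSE)
  structure(list(cost_adherent = cost_adherent,
                 cost_nonadherent = cost_nonadherent,
                 followup_cost = followup_cost),
            class = "societal_costs")
}

#' Bundle all model parameters into a scenario
#'
#' A scenario collects preferences, therapy effectiveness, health-state
#' utilities, the cost distribution, the incentive scheme and societal cost
#' parameters, and is the single input to every analysis function. With the
#' default incentive scheme (bonus 0, full observability, no overhead) the
#' incentive-free model is recovered exactly.
#'
#' Money and utility share one linear scale (marginal utility of money is 1),
#' so the monetary bonus adds directly to the non-monetary cost type inside
#' the utility function.
#'
#' @param preferences a \code{\link{preferences}} object
#' @param therapy a \code{\link{therapy}} object
#' @param utilities a \code{\link{health_utilities}} object
#' @param cost_model a \code{\link{cost_model}}, e.g.
#'   \code{\link{uniform_cost_model}}
#' @param incentive an \code{\link{incentive_scheme}}; defaults to no bonus
#' @param societal a \code{\link{societal_costs}} object
#' @return an object of class \code{"scenario"}.
#' @examples
#' s <- scenario(preferences(0.8, 0.9), therapy(0.9, 0.6),
#'               health_utilities(1, 0), uniform_cost_model(0.5),
#'               societal = societal_costs(0.05, 0.01, 1))
#' adherence_probability(s, perspective = 1)  # 0.432
#' @export
scenario <- function(preferences, therapy, utilities, cost_model,
                     incentive = incentive_scheme(), societal) {
  stopifnot(inherits(preferences, "preferences"),
            inherits(therapy, "therapy"),
            inherits(utilities, "health_utilities"),
            is_cost_model(cost_model),
            inherits(incentive, "incentive_scheme"),
            inherits(societal, "societal_costs"))
  structure(list(preferences = preferences, therapy = therapy,
                 utilities = utilities, cost_model = cost_model,
                 incentive = incentive, societal = societal),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  p <- x$preferences; th <- x$therapy; u <- x$utilities
  i <- x$incentive; sc <- x$societal
  cat("Adherence scenario (three-period beta-delta model)\n")
  cat(sprintf("  preferences : beta = %g, delta = %g\n", p$beta, p$delta))
  cat(sprintf("  therapy     : p_A = %g, p_NA = %g (delta_p = %g)\n",
              th$p_adherent, th$p_nonadherent, delta_p(x)))
  cat(sprintf("  utilities   : u_h = %g, u_s = %g (delta_u = %g)\n",
              u$u_healthy, u$u_sick, delta_u(x)))
  cat("  cost model  : ", class(x$cost_model)[1], "\n", sep = "")
  cat(sprintf("  incentive   : b = %g, p_D = %g, lambda = %g\n",
              i$bonus, i$detection_prob, i$admin_share))
  cat(sprintf("  societal    : C_A = %g, C_NA = %g, C_F = %g\n",
              sc$cost_adherent, sc$cost_nonadherent, sc$followup_cost))
  invisible(x)
}

# internal shorthands used throughout
delta_p <- function(scenario) {
  scenario$therapy$p_adherent - scenario$therapy$p_nonadherent
}
delta_u <- function(scenario) {
  scenario$utilities$u_healthy - scenario$utilities$u_sick
}

#' Replace components of a scenario
#'
#' Returns a copy of \code{scenario} with the named components (or individual
#' parameters) replaced, re-running all validity checks. Accepted names are
#' the component names (\code{preferences}, \code{therapy}, \code{utilities},
#' \code{cost_model}, \code{incentive}, \code{societal}) and the scalar
#' shortcuts \code{beta}, \code{delta}, \code{bonus}, \code{detection_prob},
#' \code{admin_share}, \code{c_max} (uniform cost model only) and
#' \code{followup_cost}.
#'
#' @param scenario a \code{\link{scenario}}
#' @param ... named replacements
#' @return a new validated \code{scenario}.
#' @export
update_scenario <- function(scenario, ...) {
  stopifnot(inherits(scenario, "scenario"))
  repl <- list(...)
  comp <- list(preferences = scenario$preferences, therapy = scenario$therapy,
               utilities = scenario$utilities, cost_model = scenario$cost_model,
               incentive = scenario$incentive, societal = scenario$societal)
  for (nm in names(repl)) {
    v <- repl[[nm]]
    switch(nm,
      preferences = , therapy = , utilities = , cost_model = ,
      incentive = , societal = { comp[[nm]] <- v },
      beta  = { comp$preferences <- preferences(v, comp$preferences$delta) },
      delta = { comp$preferences <- preferences(comp$preferences$beta, v) },
      bonus = { comp$incentive <- incentive_scheme(v,
                  comp$incentive$detection_prob, comp$incentive$admin_share) },
      detection_prob = { comp$incentive <- incentive_scheme(
                  comp$incentive$bonus, v, comp$incentive$admin_share) },
      admin_share = { comp$incentive <- incentive_scheme(
                  comp$incentive$bonus, comp$incentive$detection_prob, v) },
      c_max = {
        if (!inherits(comp$cost_model, "uniform_cost_model"))
          stop("`c_max` can only be set on a uniform cost model", call. = FALSE)
        comp$cost_model <- uniform_cost_model(v)
      },
      followup_cost = { comp$societal <- societal_costs(
                  comp$societal$cost_adherent, comp$societal$cost_nonadherent,
                  v) },
      stop("unknown scenario parameter: `", nm, "`", call. = FALSE)
    )
  }
  scenario(comp$preferences, comp$therapy, comp$utilities, comp$cost_model,
           comp$incentive, comp$societal)
}
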