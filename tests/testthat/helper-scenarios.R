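# Shared fixtures and independent oracles for the test suite.

# Reference scenario: beta = 0.8, delta = 0.9, p_A = 0.9, p_NA = 0.6,
# u_h = 1, u_s = 0, uniform costs on [0, 0.5], C_A = 0.05, C_NA = 0.01,
# C_F = 1. Thresholds 0.216 / 0.27, F(acting) = 0.432.
s0_scenario <- function(bonus = 0, detection_prob = 1, admin_share = 0,
                        beta = 0.8, delta = 0.9, c_max = 0.5,
                        followup_cost = 1) {
  scenario(preferences(beta, delta),
           therapy(0.9, 0.6),
           health_utilities(1, 0),
           uniform_cost_model(c_max),
           incentive_scheme(bonus, detection_prob, admin_share),
           societal_costs(0.05, 0.01, followup_cost))
}

# Random scenario generator (uses the current RNG stream; callers set the
# seed). With interior = TRUE the planning-perspective threshold lies
# strictly inside the cost support, so both welfare branches are on the
# quadratic piece.
random_scenario <- function(interior = TRUE, bonus = 0, detection_prob = 1,
                            admin_share = 0) {
  beta <- runif(1, 0.2, 0.95)
  delta <- runif(1, 0.5, 1)
  p_na <- runif(1, 0.1, 0.5)
  p_a <- p_na + runif(1, 0.1, min(0.45, 0.99 - p_na))
  u_s <- runif(1, 0, 0.5)
  u_h <- u_s + runif(1, 0.5, 1.5)
  ddpdu <- delta * (p_a - p_na) * (u_h - u_s)
  theta0 <- ddpdu + detection_prob * max(bonus, 0)
  c_max <- if (interior) theta0 * runif(1, 1.15, 2) else runif(1, 0.3, 2)
  c_na <- runif(1, 0, 0.05)
  c_a <- c_na + runif(1, 0.01, 0.1)
  c_f <- runif(1, 0.2, 2)
  scenario(preferences(beta, delta), therapy(p_a, p_na),
           health_utilities(u_h, u_s), uniform_cost_model(c_max),
           incentive_scheme(bonus, detection_prob, admin_share),
           societal_costs(c_a, c_na, c_f))
}

# Random scenario on which the closed-form optimal bonus is feasible,
# strictly positive and interior (p_D = 1, lambda as given). The cost
# support is sized after the fact so that beta*delta*dp*du + b* < c_max.
random_feasible_scenario <- function(admin_share = 0) {
  for (i in 1:1000) {
    beta <- runif(1, 0.3, 0.95)
    delta <- runif(1, 0.6, 1)
    p_na <- runif(1, 0.1, 0.5)
    p_a <- p_na + runif(1, 0.1, min(0.45, 0.99 - p_na))
    u_s <- 0
    u_h <- runif(1, 0.5, 1.5)
    a <- beta * delta * (p_a - p_na) * u_h
    c_na <- runif(1, 0, 0.05)
    c_a <- c_na + runif(1, 0.01, 0.1)
    c_f <- runif(1, 0.2, 2)
    b_cf <- (delta * (p_a - p_na) * c_f - (c_a - c_na) -
               a * admin_share) / (1 + 2 * admin_share)
    if (b_cf < 0.01) next
    c_max <- (a + b_cf) * runif(1, 1.1, 1.6)
    s <- scenario(preferences(beta, delta), therapy(p_a, p_na),
                  health_utilities(u_h, u_s), uniform_cost_model(c_max),
                  incentive_scheme(0, 1, admin_share),
                  societal_costs(c_a, c_na, c_f))
    if (bonus_feasibility(s)) return(s)
  }
  stop("failed to generate a feasible scenario")
}

# --- independent quadrature oracles (integrate the density directly, never
# --- the package's closed-form CDF/partial-mean) ------------------------

adherence_prob_quad <- function(s, perspective = 1) {
  theta <- adherence_threshold(s, perspective)
  hi <- min(max(theta, 0), cost_support_upper(s$cost_model))
  if (hi <= 0) return(0)
  stats::integrate(function(c) cost_pdf(s$cost_model, c), 0, hi,
                   abs.tol = 1e-12, rel.tol = 1e-12)$value
}

partial_mean_quad <- function(s, hi) {
  hi <- min(max(hi, 0), cost_support_upper(s$cost_model))
  if (hi <= 0) return(0)
  stats::integrate(function(c) c * cost_pdf(s$cost_model, c), 0, hi,
                   abs.tol = 1e-12, rel.tol = 1e-12)$value
}

individual_welfare_quad <- function(s) {
  theta <- adherence_threshold(s, 1)
  -partial_mean_quad(s, theta) + adherence_prob_quad(s, 1) * theta +
    (1 - s$incentive$detection_prob) * s$incentive$bonus
}

societal_welfare_quad <- function(s) {
  f <- adherence_prob_quad(s, 1)
  sc <- s$societal
  k <- sc$cost_adherent - sc$cost_nonadherent -
    (s$therapy$p_adherent - s$therapy$p_nonadherent) *
    s$preferences$delta * sc$followup_cost
  payout <- f + (1 - f) * (1 - s$incentive$detection_prob)
  -sc$cost_nonadherent - f * k -
    payout * (1 + s$incentive$admin_share) * s$incentive$bonus
}

total_welfare_quad <- function(s) {
  individual_welfare_quad(s) + societal_welfare_quad(s)
}
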