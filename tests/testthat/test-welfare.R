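test_that("expected cost among adherents is the truncated mean, 0 when nobody adheres", {
  expect_equal(expected_cost_given_adherent(s0_scenario()), 0.108)
  # threshold beyond the support: all adhere, mean cost is c_max / 2
  expect_equal(expected_cost_given_adherent(s0_scenario(c_max = 0.2)), 0.1)
  # beta = 0, no bonus: the adherent set is empty, value 0 by convention
  expect_equal(expected_cost_given_adherent(s0_scenario(beta = 0)), 0)
})

test_that("individual welfare matches the uniform closed form on both branches", {
  expect_equal(individual_welfare(s0_scenario()), 0.216^2 / (2 * 0.5))
  expect_equal(individual_welfare(s0_scenario()), 0.046656)
  # present-bias limit: no-one adheres, the contract is worthless
  expect_identical(individual_welfare(s0_scenario(beta = 0)), 0)
  # bonus with partial detection: quadratic branch plus the leakage term
  expect_equal(individual_welfare(s0_scenario(bonus = 0.1, detection_prob = 0.5)),
               0.266^2 / (2 * 0.5) + 0.5 * 0.1)  # 0.120756
  # saturated branch: -c_max/2 + beta*delta*dp*du + b
  s_sat <- s0_scenario(bonus = 0.4)  # threshold 0.616 >= 0.5
  expect_equal(individual_welfare(s_sat), -0.25 + 0.216 + 0.4, tolerance = 1e-12)
})

test_that("societal welfare prices prophylaxis, averted follow-up costs and the payout", {
  expect_equal(societal_welfare(s0_scenario()),
               -0.432 * 0.05 - 0.568 * 0.01 + 0.432 * 0.27)  # 0.08936
  # a fully detected bonus of 0.23 exactly offsets the prevention net gain
  expect_equal(societal_welfare(s0_scenario(bonus = 0.23)), -0.01)
  # vanishing therapy effect: welfare degenerates to the pure treatment bill
  s_null <- scenario(preferences(0.8, 0.9), therapy(0.5 + 1e-9, 0.5),
                     health_utilities(1, 0), uniform_cost_model(0.5),
                     societal = societal_costs(0.05, 0.01, 1))
  f <- adherence_probability(s_null, 1)
  expect_equal(societal_welfare(s_null), -(f * 0.05 + (1 - f) * 0.01),
               tolerance = 1e-6)
})

test_that("total welfare is the sum of its parts and matches the quadratic closed form", {
  expect_equal(total_welfare(s0_scenario()), 0.046656 + 0.08936)  # 0.136016
  sb <- s0_scenario(bonus = 0.23)
  expect_equal(total_welfare(sb), 0.188916)
  expect_equal(total_welfare_closed_form(sb), 0.188916)
  # heavy administrative overhead makes the same bonus welfare-destroying
  expect_lt(total_welfare(s0_scenario(bonus = 0.23, admin_share = 10)),
            total_welfare(s0_scenario()))
  expect_error(total_welfare_closed_form(s0_scenario(detection_prob = 0.5)),
               "detection_prob")
  expect_error(total_welfare_closed_form(s0_scenario(bonus = 0.4)),
               "incomplete")
})

test_that("closed forms agree with density quadrature on random scenarios", {
  set.seed(71)
  for (i in 1:60) {
    s <- random_scenario(interior = sample(c(TRUE, FALSE), 1),
                         bonus = runif(1, -0.05, 0.25),
                         detection_prob = runif(1),
                         admin_share = runif(1, 0, 0.5))
    expect_equal(individual_welfare(s), individual_welfare_quad(s),
                 tolerance = 1e-9)
    expect_equal(societal_welfare(s), societal_welfare_quad(s),
                 tolerance = 1e-9)
    expect_equal(total_welfare(s), total_welfare_quad(s), tolerance = 1e-9)
  }
})

test_that("with no administrative overhead the bonus is a pure redistribution", {
  # total welfare assembled without any payout transfer term must equal
  # W^I + W^S whenever lambda = 0
  set.seed(81)
  for (i in 1:25) {
    s <- random_scenario(bonus = runif(1, 0, 0.2), detection_prob = runif(1))
    theta <- adherence_threshold(s, 1)
    f <- adherence_prob_quad(s, 1)
    a <- s$preferences$beta * s$preferences$delta *
      (s$therapy$p_adherent - s$therapy$p_nonadherent) *
      (s$utilities$u_healthy - s$utilities$u_sick)
    sc <- s$societal
    k <- sc$cost_adherent - sc$cost_nonadherent -
      (s$therapy$p_adherent - s$therapy$p_nonadherent) *
      s$preferences$delta * sc$followup_cost
    w_no_transfer <- -partial_mean_quad(s, theta) + f * a -
      sc$cost_nonadherent - f * k
    expect_equal(total_welfare(s), w_no_transfer, tolerance = 1e-9)
  }
})

test_that("individual welfare rises with self-control and societal welfare follows the sign rule", {
  s0 <- s0_scenario()
  betas <- seq(0.1, 1, by = 0.1)
  wi <- vapply(betas, function(b) individual_welfare(update_scenario(s0, beta = b)),
               numeric(1))
  expect_true(all(diff(wi) > 0))
  # here C_A - C_NA - dp*delta*C_F = 0.04 - 0.27 < 0: society gains from beta
  ws <- vapply(betas, function(b) societal_welfare(update_scenario(s0, beta = b)),
               numeric(1))
  expect_true(all(diff(ws) > 0))
  # reversed cost structure: expensive prophylaxis, cheap illness
  s_rev <- update_scenario(s0, societal = societal_costs(0.3, 0.01, 0.05))
  ws_rev <- vapply(betas, function(b)
    societal_welfare(update_scenario(s_rev, beta = b)), numeric(1))
  expect_true(all(diff(ws_rev) < 0))
})

test_that("individual welfare is continuous in beta across the saturation boundary", {
  # boundary where beta*delta*dp*du + p_D*b = c_max
  s <- s0_scenario(c_max = 0.2)
  beta_b <- 0.2 / (0.9 * 0.3 * 1)
  lo <- individual_welfare(update_scenario(s, beta = beta_b - 1e-8))
  hi <- individual_welfare(update_scenario(s, beta = beta_b + 1e-8))
  expect_equal(lo, hi, tolerance = 1e-6)
})

test_that("the optimal bonus matches the first-order condition and maximizes welfare", {
  s0 <- s0_scenario()
  sol <- optimal_bonus(s0)
  expect_equal(sol$b_star, 0.27 - 0.04)  # 0.23
  expect_equal(sol$welfare, 0.188916)
  expect_true(sol$feasible)
  expect_true(sol$interior)
  # overhead version of the first-order condition
  sol_l <- optimal_bonus(s0_scenario(admin_share = 0.1))
  expect_equal(sol_l$b_star, (0.27 - 0.04 - 0.1 * 0.216) / 1.2)
  # numeric maximizer agrees with the closed form
  num <- optimal_bonus(s0, method = "numeric")
  expect_equal(num$b_star, 0.23, tolerance = 1e-6)
  # no grid point beats the reported maximizer
  grid <- seq(0, 0.5, length.out = 1000)
  w <- vapply(grid, function(b) total_welfare(update_scenario(s0, bonus = b)),
              numeric(1))
  expect_true(all(w <= sol$welfare + 1e-12))
})

test_that("optimal bonus handles partial observability and infeasible overhead", {
  # partial detection has no closed form; the numeric search must still
  # return a welfare maximum over the bracket
  s_pd <- s0_scenario(detection_prob = 0.7)
  sol <- optimal_bonus(s_pd)
  expect_equal(sol$method, "numeric")
  b_grid <- seq(0, 1, length.out = 500)
  w_grid <- vapply(b_grid, function(b)
    total_welfare(update_scenario(s_pd, bonus = b)), numeric(1))
  expect_gte(sol$welfare, max(w_grid) - 1e-8)
  # infeasible overhead: warning, constrained maximizer collapses to b = 0
  s_inf <- s0_scenario(admin_share = 5)
  expect_false(bonus_feasibility(s_inf))
  expect_warning(sol_inf <- optimal_bonus(s_inf), "feasibility")
  expect_false(sol_inf$feasible)
  expect_equal(sol_inf$b_star, 0)
  # vanishing numerator (delta*dp*C_F = C_A - C_NA): the best bonus is none
  s_zero <- update_scenario(s0_scenario(),
                            societal = societal_costs(0.05, 0.01, 0.04 / 0.27))
  sol0 <- suppressWarnings(optimal_bonus(s_zero))
  expect_equal(sol0$b_star, 0, tolerance = 1e-8)
})

test_that("the overhead feasibility bound is strict and guards beta = 0", {
  expect_true(bonus_feasibility(s0_scenario()))            # 0 < 0.23/0.216
  bound <- (0.27 - 0.04) / 0.216
  expect_false(bonus_feasibility(s0_scenario(admin_share = bound)))
  expect_true(bonus_feasibility(s0_scenario(admin_share = bound - 1e-9)))
  # no follow-up costs to avert: never feasible
  expect_false(bonus_feasibility(s0_scenario(followup_cost = 0)))
  # degenerate denominator at beta = 0: report the sign of the numerator
  expect_true(bonus_feasibility(s0_scenario(beta = 0)))
  expect_false(bonus_feasibility(s0_scenario(beta = 0, followup_cost = 0)))
})

test_that("welfare reports are internally consistent", {
  set.seed(91)
  for (i in 1:20) {
    s <- random_scenario(bonus = runif(1, -0.05, 0.2), detection_prob = runif(1))
    rep <- welfare_report(s)
    expect_equal(rep$total, rep$individual + rep$societal, tolerance = 1e-10)
    # W^I = F * (-E^A[c] + theta) + (1 - p_D) b
    theta <- adherence_threshold(s, 1)
    expect_equal(rep$individual,
                 rep$adherence_prob * (-rep$expected_cost_adherent + theta) +
                   (1 - s$incentive$detection_prob) * s$incentive$bonus,
                 tolerance = 1e-10)
  }
})

test_that("co-payments lower adherence and individual welfare, never raise them", {
  s0 <- s0_scenario()
  cp0 <- copayment_report(s0, 0)
  expect_equal(cp0$delta$adherence_prob, 0)
  expect_equal(cp0$delta$individual, 0)
  expect_equal(cp0$delta$total, 0)
  cp <- copayment_report(s0, 0.05)
  expect_equal(cp$delta$adherence_prob, (0.216 - 0.05) / 0.5 - 0.432)  # -0.1
  # a crushing co-payment eliminates adherence entirely
  cp_big <- copayment_report(s0, 1)
  expect_equal(cp_big$with_copay$adherence_prob, 0)
  set.seed(101)
  for (i in 1:20) {
    s <- random_scenario(detection_prob = runif(1))
    cp <- copayment_report(s, runif(1, 0, 0.4))
    expect_lte(cp$delta$adherence_prob, 0)
    expect_lte(cp$delta$individual, 1e-12)
  }
})
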