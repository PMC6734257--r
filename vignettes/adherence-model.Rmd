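---
title: "A beta-delta decision model of adherence to prophylactic therapy"
author: "adherebd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A beta-delta decision model of adherence to prophylactic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherebd)
```

## The decision problem

Prophylactic therapy — antihypertensives, statins, maintenance
antidepressants, depot antipsychotics — asks an asymptomatic person to pay a
cost now for a health benefit that arrives later and only probabilistically.
`adherebd` models this as a three-period problem. At `t = 0` the individual,
healthy, accepts a treatment contract and then learns their *cost type* `c`:
the non-monetary burden adherence would impose on them (time, side effects,
distress), drawn from a distribution `F` with density `f` that captures the
heterogeneity of this burden across a population. At `t = 1`, still healthy,
they either take the therapy (adherence, bearing `c`) or refuse it. At
`t = 2` they remain healthy with probability `p_A` if they adhered and
`p_NA < p_A` otherwise; the two health states are valued `u_h > u_s`.

Time preferences are quasi-hyperbolic: period weights `1, βδ, βδ²` with an
exponential factor `δ ∈ (0, 1]` and a present-bias weight `β ∈ (0, 1]`.
With `β = 1` the model collapses to standard exponential discounting and
behaviour is time-consistent. With `β < 1` everything that is not immediate
is shrunk by the same extra factor, and a decision evaluated *before* the
moment of action looks different from the same decision evaluated *at* that
moment — the formal engine behind patients abandoning therapies they
sincerely intended to follow.

Writing `Δp = p_A − p_NA` and `Δu = u_h − u_s`, comparing the two branches'
intertemporal utilities (`intertemporal_utility()`) gives threshold rules:

* planned (perspective `t = 0`): adhere iff `c ≤ δ Δp Δu`;
* actual (perspective `t = 1`): adhere iff `c ≤ βδ Δp Δu`.

Ties adhere: the criterion is a weak inequality, and `decide()` implements
it as such. Population adherence probabilities are the CDF at these
thresholds (`adherence_probability()`); their difference,
`self_control_gap()`, is strictly positive whenever `β < 1` and the density
is positive between the two thresholds.

A financial incentive pays adherents a bonus `b`; a non-adherent claimant
escapes detection with probability `1 − p_D` and then collects the bonus
too. Both thresholds shift by `p_D · b`. Sanctioning non-adherence with a
fine of the same magnitude and the same detection probability shifts the
threshold identically, so only the bonus form is implemented. A co-payment
is the same object with `b < 0`; for a co-payment, "detection" means the
charge is actually enforced on a non-adherent, so a non-adherent still pays
with probability `1 − p_D`. This keeps one formula — non-adherents receive
`(1 − p_D)·b` in expectation — valid for both signs of `b`.

## Welfare

All welfare is measured from the acting perspective `t = 1`, net of the
contract-rejection baseline (rejection is behaviourally identical to
acceptance followed by non-adherence, without the bonus). We deliberately do
not add a second, long-run (`β = 1`) normative criterion: the model's
welfare statements are about what the individual experiences at the moment
of choice, and mixing normative standards would make the incentive analysis
ambiguous.

With `θ = βδ Δp Δu + p_D b`:

* `individual_welfare()`: `W^I = −∫₀^θ c f(c) dc + F(θ)·θ + (1 − p_D)·b`;
* `societal_welfare()`: `W^S = −C_NA − F(θ)·(C_A − C_NA − Δp δ C_F)
  − [F(θ) + (1 − F(θ))(1 − p_D)]·(1 + λ)·b`;
* `total_welfare()`: `W = W^I + W^S`.

`C_A` and `C_NA` are society's treatment expenses at `t = 1` for adherent
and non-adherent patients (`C_NA < C_A`), `C_F` the follow-up cost of
illness at `t = 2`, and `λ ≥ 0` the administrative overhead per unit of
bonus paid. Society discounts with `δ` only: its welfare is a monetary
aggregate, and the printed societal expression carries no `β`. Note the
asymmetry this creates deliberately: individual impatience is a preference,
societal discounting is an accounting convention.

With `λ = 0` the bonus itself is a pure transfer — it cancels between
`W^I` and `W^S` and affects `W` only through the adherence margin. Under
full observability (`p_D = 1`), uniform costs and an interior threshold,
`W` is a concave quadratic in `b` and the first-order condition gives

```
b* = [δ Δp C_F − (C_A − C_NA) − βδ Δp Δu · λ] / (1 + 2λ),
```

returned by `optimal_bonus()` whenever those conditions hold. A bonus can
raise welfare at all only if `λ < (δ Δp C_F − (C_A − C_NA)) / (βδ Δp Δu)`
(`bonus_feasibility()`, strict inequality; at `β = 0` the denominator
vanishes and the condition degenerates to the sign of the numerator).

## Parameters at a glance

| Parameter | Meaning | Range | Notes |
|---|---|---|---|
| `beta` | present-bias weight | `[0, 1]` | 1 = time-consistent; 0 admitted as a limiting value for welfare analysis even though the behavioural model motivates `(0, 1]` |
| `delta` | discount factor per period | `(0, 1]` | one period ≈ one treatment decision cycle |
| `p_adherent`, `p_nonadherent` | `P(healthy at t = 2)` | `0 ≤ p_NA < p_A ≤ 1` | `Δp` is the therapy's effectiveness |
| `u_healthy`, `u_sick` | health-state utilities | `u_h > u_s` | only `Δu` matters for decisions |
| `c_max` | uniform cost-support bound | `> 0` | sets the scale of cost heterogeneity |
| `bonus` | adherence bonus | any | `< 0` = co-payment |
| `detection_prob` | `P(bonus abuse detected)` | `[0, 1]` | 1 = full observability |
| `admin_share` | overhead per unit bonus | `≥ 0` | the `λ` of the feasibility bound |
| `cost_adherent`, `cost_nonadherent`, `followup_cost` | societal costs | `≥ 0`, `C_NA < C_A` | money units |

Money and utility share one linear scale (marginal utility of money = 1):
the model adds the monetary bonus directly to the non-monetary cost inside
the utility function, so `b`, `c`, `Δu` and the `C` parameters are all in
the same dimensionless unit. That is a convention, not a measurement claim;
applications that need a conversion rate should rescale `Δu`.

The horizon is fixed at three periods. Heterogeneity lives in the cost type
only: each scenario has a single `(β, δ)` pair. Whether the `t = 0` self
anticipates its own present bias (sophistication) is not modelled — the two
perspectives are simply both computed — and no commitment devices, belief
updating, repeated decisions or anticipation utility are included.

## The reference parameterisation

Throughout the tests and examples we use a single reference scenario:
`β = 0.8`, `δ = 0.9`, `p_A = 0.9`, `p_NA = 0.6`, `u_h = 1`, `u_s = 0`,
uniform costs on `[0, 0.5]`, `C_A = 0.05`, `C_NA = 0.01`, `C_F = 1`. It was
chosen once, before any validation, to be clinically plausible and
analytically convenient: an effective therapy (`Δp = 0.3`), moderate present
bias, incomplete adherence from both perspectives
(`δΔpΔu = 0.27 < c_max`), treatment cheap relative to the illness it
prevents (`C_A − C_NA = 0.04 ≪ ΔpδC_F = 0.27`), and round hand-checkable
outputs: thresholds 0.27/0.216, adherence 54%/43.2%, `W^I = 0.046656`,
`W^S = 0.08936`, `b* = 0.23`.

```{r reference}
s0 <- scenario(preferences(0.8, 0.9), therapy(0.9, 0.6),
               health_utilities(1, 0), uniform_cost_model(0.5),
               societal = societal_costs(0.05, 0.01, 1))
welfare_report(s0)
optimal_bonus(s0)
```

## Cost models and numerical choices

The cost distribution enters through a small S3 contract: `cost_cdf()`,
`cost_pdf()`, `cost_partial_mean()` (the integral `∫ c f(c) dc` that appears
in `W^I`), `cost_sample()` and `cost_support_upper()`. The uniform model
implements all of these in closed form, so under uniform costs the
"generic" welfare code *is* the closed form — `(βδΔpΔu + p_D b)²/(2c_max)`
on the interior branch — to machine precision, with no special-casing.

Other models need only a CDF, density and sampler; the defaults then supply:

* **partial means** by adaptive quadrature (`stats::integrate`, absolute
  tolerance `1e-10`), truncated at the effective support bound;
* **support bounds** as the point where the CDF reaches `1 − 1e-12`
  (doubling search plus root refinement), which truncates unbounded
  supports with negligible mass loss;
* thresholds may fall outside the support — a large co-payment drives the
  threshold negative, a large bonus past `c_max` — and are clamped through
  the CDF rather than rejected, so sweeps and optimizers can cross those
  boundaries freely.

`optimal_bonus()` uses the closed form on its validity domain and otherwise
a coarse grid (10,000 points by default) over `[0, b_upper]` with
golden-section refinement (`stats::optimize`, tolerance `1e-8`) in the
winning bracket; `b_upper` defaults to the bonus that already guarantees
full adherence plus one support width, beyond which welfare cannot improve.
Boundary solutions are reported with `interior = FALSE` rather than
truncated or hidden, since the model itself is silent on whether `b*`
should be kept interior. Derivative checks in `marginal_adherence_wrt_bonus()`
refuse thresholds within `1e-9` of a support edge, where the CDF has a kink.

Degenerate inputs follow the model's own limits: `E^A[c]` is defined as 0
when nobody adheres (the defining ratio is 0/0 there), which makes
`W^I = (1 − p_D)·b` in that case; `β = 0` is accepted so the
full-present-bias welfare limit can be evaluated exactly.

## The simulator: what it emulates and what it does not

`simulate_population()` is the agent-based counterpart of the closed forms
and their validation harness (`mc_vs_analytic()` attaches z-scores). Each
agent accepts the contract, draws a cost type, decides by the
acting-perspective threshold, transitions to the `t = 2` state, and — if a
bonus is active and the agent non-adherent — has their improper claim
detected with probability `p_D`. One root seed spawns three child streams
(costs, health, detection), so enabling detection does not perturb the cost
draws, and runs are bit-reproducible.

Per-agent welfare contributions are measured against the rejection
baseline. By default the `t = 2` health term enters as its conditional
expectation given the decision (the baseline's health path is a
counterfactual that is never realized, and using expectations for both
sides removes that variance without bias); bonus payouts and detection are
always realized draws. `realized = TRUE` switches to fully realized health
outcomes for stress testing — same estimands, larger standard errors.

The generator emulates exactly the model's assumptions: one decision, cost
heterogeneity only, independent agents, constant transition probabilities,
perfectly known parameters. Real adherence data feature repeated decisions,
state dependence, measurement error in adherence itself, peer and provider
effects, and parameter uncertainty — none of which are simulated. Passing
Monte Carlo checks therefore validate the *implementation* of this model,
not the model's fit to any cohort.

Validation sizes were chosen to keep the full suite at desk scale: single
runs use `n = 1e5` agents (binomial standard error ≈ 0.0016 on the
reference adherence probability), the seed-sweep check runs 11 scenarios ×
20 seeds at `n = 1e5` expecting ≥ 95% of |z| ≤ 3 checks to pass, and the
convergence test fits the error slope over `n ∈ {10³, 10⁴, 10⁵}` with 20
seeds per size, accepting a slope in `[−0.7, −0.3]` around the theoretical
`−1/2`.

## Comparative statics

`marginal_adherence_wrt_bonus()` and `societal_welfare_beta_derivative()`
return the analytic derivatives `dF/db = f(θ)·p_D` and
`∂W^S/∂β = −f(βδΔpΔu)·δΔpΔu·(C_A − C_NA − Δp δ C_F)`; the test suite
verifies both against central finite differences (step `1e-6`, relative
tolerance `1e-4`) on random interior scenarios. The second derivative's
sign rule is the model's key policy comparative static: society gains from
patient self-control exactly when illness is expensive relative to
prophylaxis. `parameter_sweep()` tabulates adherence (both perspectives),
the self-control gap and all three welfare quantities along a grid of any
one parameter, re-validating invariants per grid point and skipping invalid
points with a warning (so a β grid may touch 0, but a δ grid cannot touch
2). On the interior branch `W^I ∝ β²` — present bias hurts individual
welfare quadratically, one of the model's sharpest testable statements.

## Known limitations

* One decision, three periods: no dynamics of habit, no learning, no
  repeated incentives.
* The single money-utility scale makes welfare comparisons across scenarios
  with different `Δu` delicate; only within-scenario comparisons are
  meaningful without a calibration step.
* The welfare criterion inherits the `t = 1` perspective; analysts who
  prefer a long-run criterion should evaluate `β = 1` counterfactuals
  explicitly.
* `W^S` is linear in costs: no budget constraints, no insurer objective,
  no targeting of the bonus by cost type.
* The closed-form `b*` requires `p_D = 1`; under partial observability only
  the numeric maximizer is available, and the feasibility bound is then
  conservative guidance rather than an exact condition.
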