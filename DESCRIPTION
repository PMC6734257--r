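Package: adherebd
Title: Medication Adherence Under Quasi-Hyperbolic Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-period decision model of adherence to prophylactic
    therapy for individuals with time-inconsistent (beta-delta,
    quasi-hyperbolic) preferences. Implements the individual's intertemporal
    utilities, adherence thresholds and probabilities from the planning
    (t = 0) and acting (t = 1) perspectives, the self-control gap, individual
    and societal welfare with closed forms under uniformly distributed
    treatment costs, the design of financial incentives (bonus, detection
    probability, administration overhead) including the welfare-maximizing
    bonus, co-payments as negative bonuses, comparative statics with
    finite-difference verification, and an agent-based Monte Carlo simulator
    that validates the closed forms. A command-line interface evaluates
    scenarios from JSON or YAML configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
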