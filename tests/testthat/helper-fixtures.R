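# Shared fixture builders. Everything is generated in code at test time.

# admissible parameter sets used by the property tests
fam_test_params <- list(
  "exponential"       = c(rate = 0.07),
  "weibull"           = c(shape = 1.4, scale = 14),
  "gamma"             = c(shape = 2, rate = 0.15),
  "log-logistic"      = c(shape = 1.7, scale = 9),
  "log-normal"        = c(meanlog = 2.2, sdlog = 0.9),
  "gompertz"          = c(rate = 0.02, shape = 0.06),
  "generalized-gamma" = c(mu = 2.4, sigma = 0.7, Q = -0.4),
  "generalized-F"     = c(mu = 2.3, sigma = 0.7, Q = 0.4, P = 0.8)
)

# a minimal but valid digitized curve (exponential shape, no noise)
toy_curve <- function(endpoint = "OS", arm = "control", rate = 0.05,
                      months = 12, n0 = 50) {
  tt <- 0:months
  s <- exp(-rate * tt)
  digitized_curve(endpoint, arm, tt, s, risk_times = c(0, months),
                  n_at_risk = c(n0, max(1, round(n0 * s[months + 1]))))
}

toy_curve_set <- function(rate_os = 0.04, rate_pfs = 0.08) {
  list(os_intervention = toy_curve("OS", "intervention", rate_os),
       os_control = toy_curve("OS", "control", rate_os),
       pfs_intervention = toy_curve("PFS", "intervention", rate_pfs),
       pfs_control = toy_curve("PFS", "control", rate_pfs))
}

# exponential fit with an exact, chosen rate: one event at time 1/rate
exact_exp_fit <- function(rate) {
  fit_parametric(psm_ipd(1 / rate, 1), "exponential")
}

# bare-bones model inputs for engine-level tests (no costs by default)
toy_inputs <- function(hr_os = 1, hr_pfs = 1, discount = 0, horizon = 100,
                       utilities = list(u_pfs_intervention = 1,
                                        u_pfs_control = 1, u_pps = 1),
                       resources = list(), dsa_ranges = list()) {
  model_inputs(toy_curve_set(), hr_os, hr_pfs, discount, horizon,
               utilities, resources, dsa_ranges)
}

flat_cost_item <- function(name, arm, state, unit_cost, per_month = 1) {
  resource_item(name, arm, state, unit_cost,
                schedule_phase(per_month, "per-month"))
}
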