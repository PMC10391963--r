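# IPD reconstruction from digitized coordinates and the product-limit
# estimator used to validate it.

test_that("flat curve reconstructs to all-censored records", {
  dc <- digitized_curve("OS", "control", c(0, 6, 12), c(1, 1, 1),
                        risk_times = c(0, 12), n_at_risk = c(10, 10))
  ipd <- reconstruct_ipd(dc)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event), 0)
  expect_true(all(ipd$time == 12))
})

test_that("single drop with one risk entry forces the event count", {
  dc <- digitized_curve("OS", "control", c(0, 3), c(1, 0.5),
                        risk_times = 0, n_at_risk = 10)
  ipd <- reconstruct_ipd(dc)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event), 5)           # 1 - d/10 = 0.5
  expect_true(all(ipd$time == 3))
  expect_equal(sum(ipd$event == 0), 5)      # rest censored at end of follow-up
})

test_that("round trip: reconstructed KM matches the digitized curve", {
  set.seed(99)
  tt <- rexp(200, 0.05)
  ipd0 <- psm_ipd(pmin(tt, 30), as.integer(tt <= 30))
  dc <- digitize(ipd0, grid = 0:30, risk_times = seq(0, 30, 6),
                 with_events = TRUE)
  ipd1 <- reconstruct_ipd(dc)
  expect_equal(nrow(ipd1), dc$n_at_risk[1])
  expect_lt(max(abs(km_curve(ipd1)$S(dc$times) - dc$surv_probs)), 0.02)
  # subjects conserved and event budget honoured (total_events supplied)
  expect_equal(sum(ipd1$event), dc$total_events)
  expect_true(all(ipd1$time <= max(dc$times)))
})

test_that("reconstruction hits published numbers at risk exactly", {
  set.seed(42)
  sim <- simulate_trial(trial_spec(n_per_arm = 150, seed = 42))
  for (nm in names(sim$ipd)) {
    dc <- digitize(sim$ipd[[nm]], grid = 0:30, risk_times = seq(0, 30, 6))
    ipd <- reconstruct_ipd(dc)
    for (j in seq_along(dc$risk_times)) {
      t_j <- dc$risk_times[j]
      # at risk at t: neither event nor censoring strictly before t
      expect_equal(sum(ipd$time > t_j) +
                     sum(ipd$time == t_j & ipd$event == 0),
                   dc$n_at_risk[j],
                   info = sprintf("%s at month %g", nm, t_j))
    }
  }
})

test_that("infeasible risk tables are refused with the offending interval", {
  # published n at risk *rises* against an 80% survival drop: unattainable
  dc <- digitized_curve("OS", "control", c(0, 3, 6), c(1, 0.2, 0.2),
                        risk_times = c(0, 6), n_at_risk = c(10, 10))
  err <- tryCatch(reconstruct_ipd(dc), error = identity)
  expect_s3_class(err, "psmforge_reconstruction_infeasible")
  expect_match(conditionMessage(err), "interval 1")
})

test_that("km_curve matches a hand-computed product limit", {
  # 6 records, mixed censoring; oracle: explicit product over risk sets
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0, 1)
  km <- km_curve(psm_ipd(time, event))
  oracle_S <- function(t) {
    s <- 1
    for (u in sort(unique(time[event == 1]))) {
      if (u > t) break
      n_risk <- sum(time >= u)
      d <- sum(time == u & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  for (t in c(0, 1, 1.5, 2, 3, 4, 5)) {
    expect_equal(km$S(t), oracle_S(t), info = paste("t =", t))
  }
})

test_that("km_curve trivial cases", {
  km <- km_curve(psm_ipd(1:4, rep(1, 4)))
  expect_equal(km$S(c(1, 2, 3, 4)), c(0.75, 0.5, 0.25, 0))
  km2 <- km_curve(psm_ipd(1:4, rep(0, 4)))
  expect_equal(km2$S(c(0, 2, 4)), c(1, 1, 1))
})

test_that("curve validation rejects malformed inputs", {
  expect_error(digitized_curve("OS", "control", c(0, 1, 2), c(1, 0.8, 0.9),
                               0, 10), class = "psmforge_invalid_curve")
  expect_error(digitized_curve("OS", "control", c(0, 1), c(0.9, 0.8),
                               0, 10), class = "psmforge_invalid_curve")
  expect_error(digitized_curve("OS", "control", c(0, 1), c(1, 0.8),
                               c(0, 5), c(10, 12)),
               class = "psmforge_invalid_curve")  # rising n at risk
  expect_error(digitized_curve("OS", "control", c(0, 1), c(1, 0.8),
                               c(0, 0.5), c(10, 8)),
               class = "psmforge_invalid_curve")  # risk time off the grid
})
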