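# Partitioned survival engine: occupancy, discounting, accumulation, ICER.

test_that("discount factors", {
  expect_equal(discount_factor(0, c(0, 5, 100)), c(1, 1, 1))
  expect_equal(discount_factor(0.03, 12), 1 / 1.03, tolerance = 1e-9)
  d <- discount_factor(0.03, seq(0, 120, 0.5))
  expect_true(all(diff(d) < 0))
  expect_error(discount_factor(-0.01, 1), class = "psmforge_invalid_parameter")
})

test_that("occupancy: equal curves give zero post-progression state", {
  cv <- as_curve(exact_exp_fit(0.05))
  occ <- state_occupancy(cv, cv, 50)
  expect_true(all(abs(occ$cycle$pps) < 1e-12))
  expect_true(all(abs(rowSums(occ$cycle[, c("pfs", "pps", "dead")]) - 1) < 1e-9))
  expect_true(all(diff(occ$boundary$dead) >= -1e-12))
})

test_that("OS below PFS halts the engine, no clamping", {
  pfs <- as_curve(exact_exp_fit(0.02))
  os <- as_curve(exact_exp_fit(0.05))
  err <- tryCatch(state_occupancy(pfs, os, 10), error = identity)
  expect_s3_class(err, "psmforge_logical_inconsistency")
  expect_equal(err$cycle, 1)
  inputs <- toy_inputs()
  expect_error(run_psm(inputs, exact_exp_fit(0.02), exact_exp_fit(0.05)),
               class = "psmforge_logical_inconsistency")
})

test_that("engine life years match the exponential closed form", {
  lam <- 0.05; Tm <- 100
  inputs <- toy_inputs(discount = 0, horizon = Tm)
  res <- run_psm(inputs, exact_exp_fit(lam), exact_exp_fit(lam))
  ly_months <- res$summary$per_arm$control[["ly"]] * 12
  expect_lt(abs(ly_months - (1 - exp(-lam * Tm)) / lam), 0.05)
  # all utilities 1 => LY equals QALY
  expect_equal(res$summary$per_arm$control[["qaly"]],
               res$summary$per_arm$control[["ly"]])
  expect_true(res$summary$ly_mode)
})

test_that("half-cycle correction is second-order accurate", {
  cv <- as_curve(exact_exp_fit(0.05))
  ly1 <- psmforge:::.ly_months_fine(cv, 100, 1)
  ly_half <- psmforge:::.ly_months_fine(cv, 100, 0.5)
  expect_lt(abs(ly1 - ly_half), 0.01)
  # the engine's trapezoid equals the step-1 fine grid
  res <- run_psm(toy_inputs(discount = 0), exact_exp_fit(0.05), exact_exp_fit(0.05))
  expect_equal(res$summary$per_arm$control[["ly"]] * 12, ly1, tolerance = 1e-9)
})

test_that("midpoint correction variant stays close to trapezoid", {
  inputs <- toy_inputs(discount = 0.03)
  r1 <- run_psm(inputs, exact_exp_fit(0.06), exact_exp_fit(0.04), "trapezoid")
  r2 <- run_psm(inputs, exact_exp_fit(0.06), exact_exp_fit(0.04), "midpoint")
  expect_lt(abs(r1$summary$per_arm$control[["ly"]] -
                  r2$summary$per_arm$control[["ly"]]), 0.01)
})

test_that("discounted totals are monotone in the discount rate", {
  items <- list(flat_cost_item("a", "control", "PFS", 500),
                flat_cost_item("a", "intervention", "PFS", 500))
  prev <- Inf
  for (r in c(0, 0.015, 0.03, 0.045, 0.06)) {
    res <- run_psm(toy_inputs(discount = r, resources = items),
                   exact_exp_fit(0.06), exact_exp_fit(0.04))
    tot <- res$summary$per_arm$control[["cost_disc"]] +
      res$summary$per_arm$control[["qaly_disc"]]
    expect_lte(tot, prev + 1e-9)
    if (r == 0) {
      expect_equal(res$summary$per_arm$control[["cost_disc"]],
                   res$summary$per_arm$control[["cost"]])
    }
    prev <- tot
  }
})

test_that("hr = 1 with equal costs is a perfect null", {
  res <- run_psm(toy_inputs(hr_os = 1, hr_pfs = 1, discount = 0.03),
                 exact_exp_fit(0.06), exact_exp_fit(0.04))
  expect_lt(abs(res$summary$incremental$qaly_disc), 1e-9)
  expect_lt(abs(res$summary$incremental$cost_disc), 1e-9)
  expect_identical(res$summary$icer_status, "undefined")
})

test_that("costs scale linearly into the ICER", {
  items <- list(flat_cost_item("drug", "intervention", "PFS", 1000))
  base <- run_psm(toy_inputs(hr_os = 0.6, hr_pfs = 0.6, resources = items),
                  exact_exp_fit(0.06), exact_exp_fit(0.04))
  items2 <- list(flat_cost_item("drug", "intervention", "PFS", 2000))
  dbl <- run_psm(toy_inputs(hr_os = 0.6, hr_pfs = 0.6, resources = items2),
                 exact_exp_fit(0.06), exact_exp_fit(0.04))
  expect_equal(dbl$summary$incremental$cost, 2 * base$summary$incremental$cost)
  expect_equal(dbl$summary$icer, 2 * base$summary$icer)
})

test_that("occupancy weights costs: PPS spend follows the OS-PFS gap", {
  items <- list(flat_cost_item("next_line", "control", "PPS", 1200))
  res <- run_psm(toy_inputs(resources = items),
                 exact_exp_fit(0.08), exact_exp_fit(0.04))
  tr <- res$trace[res$trace$arm == "control", ]
  expect_equal(tr$cost, 1200 * tr$pps, tolerance = 1e-9)
})

test_that("icer sentinels", {
  expect_equal(icer(1000, 0.5), list(value = 2000, status = "ok"))
  expect_identical(icer(1000, 0)$status, "undefined")
  neg <- icer(-500, 0.5)
  expect_equal(neg$value, -1000)
  expect_identical(neg$status, "dominant")
  expect_identical(icer(500, -0.5)$status, "dominated")
})
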