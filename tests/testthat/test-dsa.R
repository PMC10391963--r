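# Univariate sensitivity analysis and tornado ordering.

dsa_setup <- function(dsa_ranges, hr_os = 0.6, hr_pfs = 0.6, discount = 0.03,
                      drug_cost = 1000) {
  inputs <- toy_inputs(hr_os = hr_os, hr_pfs = hr_pfs, discount = discount,
                       resources = list(
                         flat_cost_item("drug", "intervention", "PFS", drug_cost)),
                       dsa_ranges = dsa_ranges)
  list(inputs = inputs, pfs = exact_exp_fit(0.06), os = exact_exp_fit(0.04))
}

test_that("degenerate ranges reproduce the base ICER in every scenario", {
  s <- dsa_setup(list(hr_os = c(0.6, 0.6), discount_rate = c(0.03, 0.03),
                      "cost:drug" = c(1000, 1000)))
  d <- run_dsa(s$inputs, s$pfs, s$os)
  base <- attr(d, "base")$icer
  expect_true(all(d$status_low == "ok" & d$status_high == "ok"))
  expect_equal(d$icer_low, rep(base, 3), tolerance = 1e-12)
  expect_equal(d$icer_high, rep(base, 3), tolerance = 1e-12)
})

test_that("discount-rate low end 0 reproduces the undiscounted base totals", {
  s <- dsa_setup(list(discount_rate = c(0, 0.05)))
  d <- run_dsa(s$inputs, s$pfs, s$os)
  base <- attr(d, "base")
  i <- which(d$parameter == "discount_rate")
  expect_equal(d$icer_low[i], base$icer_undiscounted, tolerance = 1e-12)
  expect_equal(d$inc_cost_low[i], base$incremental$cost, tolerance = 1e-12)
})

test_that("ICER diverges as the OS hazard ratio approaches 1", {
  vals <- vapply(c(0.7, 0.9, 0.99), function(h) {
    s <- dsa_setup(list(), hr_os = h, hr_pfs = 1)
    run_psm(s$inputs, s$pfs, s$os)$summary$icer
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3] / vals[1], 5)  # sharp growth toward the pole
})

test_that("ICER is affine in any unit cost (3-point collinearity)", {
  s <- dsa_setup(list("cost:drug" = c(500, 1500)))
  d <- run_dsa(s$inputs, s$pfs, s$os)
  base <- attr(d, "base")$icer
  i <- which(d$parameter == "cost:drug")
  # points (500, icer_low), (1000, base), (1500, icer_high) must be collinear
  slope1 <- (base - d$icer_low[i]) / (1000 - 500)
  slope2 <- (d$icer_high[i] - base) / (1500 - 1000)
  expect_equal(slope1, slope2, tolerance = 1e-9)
})

test_that("a failing scenario is flagged and does not abort the sweep", {
  # base (hr 0.9 on both endpoints) is valid; halving the PFS hazard ratio
  # alone lifts intervention PFS above intervention OS -> engine failure
  inputs <- toy_inputs(hr_os = 0.9, hr_pfs = 0.9, discount = 0,
                       resources = list(
                         flat_cost_item("drug", "intervention", "PFS", 100)),
                       dsa_ranges = list(hr_pfs = c(0.45, 0.9),
                                         "cost:drug" = c(50, 150)))
  d <- run_dsa(inputs, exact_exp_fit(0.06), exact_exp_fit(0.04))
  i <- which(d$parameter == "hr_pfs")
  expect_identical(d$status_low[i], "engine-failure")
  expect_true(is.na(d$icer_low[i]))
  j <- which(d$parameter == "cost:drug")
  expect_true(all(c(d$status_low[j], d$status_high[j]) != "engine-failure"))
  tor <- tornado_order(d)
  expect_identical(tor$flag[tor$parameter == "hr_pfs"], "engine-failure")
  expect_equal(tor$parameter[nrow(tor)], "hr_pfs")  # failures sort last
})

test_that("one-at-a-time discipline: non-swept parameters stay at base", {
  s <- dsa_setup(list(hr_os = c(0.4, 0.8), "cost:drug" = c(500, 1500)))
  d <- run_dsa(s$inputs, s$pfs, s$os)
  # in the cost sweep the effect increment must equal the base effect
  base <- attr(d, "base")
  i <- which(d$parameter == "cost:drug")
  expect_equal(d$inc_qaly_low[i], base$incremental$qaly_disc, tolerance = 1e-12)
  expect_equal(d$inc_qaly_high[i], base$incremental$qaly_disc, tolerance = 1e-12)
})

test_that("tornado ordering: width-ranked, stable under currency rescaling", {
  s <- dsa_setup(list(hr_os = c(0.4, 0.8), "cost:drug" = c(999, 1001),
                      discount_rate = c(0, 0.05)))
  d <- run_dsa(s$inputs, s$pfs, s$os)
  tor <- tornado_order(d)
  expect_true(all(diff(tor$width[tor$flag == ""]) <= 1e-12))
  expect_equal(tor$parameter[nrow(tor)], "cost:drug")  # near-zero width last
  # multiply every cost by 10: ordering unchanged
  s2 <- dsa_setup(list(hr_os = c(0.4, 0.8), "cost:drug" = c(9990, 10010),
                       discount_rate = c(0, 0.05)), drug_cost = 10000)
  tor2 <- tornado_order(run_dsa(s2$inputs, s2$pfs, s2$os))
  expect_identical(tor$parameter, tor2$parameter)
  # include/exclude filters honoured
  expect_identical(tornado_order(d, include = "hr_os")$parameter, "hr_os")
  expect_false("hr_os" %in% tornado_order(d, exclude = "hr_os")$parameter)
})

test_that("ranges must bracket the base value", {
  expect_error(
    toy_inputs(hr_os = 0.6, dsa_ranges = list(hr_os = c(0.7, 0.9))),
    class = "psmforge_invalid_range")
})
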