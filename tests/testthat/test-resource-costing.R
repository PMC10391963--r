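# Posology schedules -> per-cycle units and costs.

test_that("dose_units handles weight-based dosing and vial wastage", {
  expect_equal(dose_units(3.6, 70, 100), 2.52)
  expect_equal(dose_units(5.4, 70, 100), 3.78)
  expect_equal(dose_units(3.6, 70, 100, "round-up-vial"), 3)
  expect_error(dose_units(0, 70, 100), class = "psmforge_invalid_parameter")
})

test_that("rate-type schedules follow the 30.4375-day month", {
  daily <- resource_item("d", "control", "PFS", 1, schedule_phase(1, "per-day"))
  expect_equal(expand_schedule(daily, 1), 365.25 / 12)
  monthly <- resource_item("m", "control", "PFS", 1, schedule_phase(1, "per-month"))
  expect_equal(expand_schedule(monthly, 12), rep(1, 12))
})

test_that("rate totals equal rate x elapsed days regardless of alignment", {
  # phase boundaries deliberately off the cycle grid
  it <- resource_item("w", "control", "PFS", 1,
                      schedule_phase(2, "per-week", phase_start = 10,
                                     phase_end = 100, phase_unit = "day"))
  u <- expand_schedule(it, 6)
  expect_equal(sum(u), 2 / 7 * 90, tolerance = 1e-9)
})

test_that("complex treatment-cycle schedule: weekly x2 cycles, q2w x4, q4w capped", {
  # 4-week treatment cycles; weekly in cycles 1-2, every 2 weeks in 3-6,
  # every 4 weeks thereafter, capped at 24 treatment cycles
  phases <- rbind(
    schedule_phase(1, "every-1-weeks", 0, 2, "txcycle", 4),
    schedule_phase(1, "every-2-weeks", 2, 6, "txcycle", 4),
    schedule_phase(1, "every-4-weeks", 6, Inf, "txcycle", 4, cap = 24))
  it <- resource_item("dara", "intervention", "PFS", 1, phases)
  u <- expand_schedule(it, 36)
  expect_equal(sum(u), 8 + 8 + 18)  # 34 administrations in total
  # per-phase counts at the phase boundaries
  expect_equal(sum(expand_schedule(resource_item("p1", "intervention", "PFS", 1,
    schedule_phase(1, "every-1-weeks", 0, 2, "txcycle", 4)), 36)), 8)
  expect_equal(sum(expand_schedule(resource_item("p2", "intervention", "PFS", 1,
    schedule_phase(1, "every-2-weeks", 2, 6, "txcycle", 4)), 36)), 8)
})

test_that("administration events conserve units across cycle boundaries", {
  it <- resource_item("q3w", "control", "PFS", 1,
                      schedule_phase(2.52, "every-3-weeks", 0, Inf, "week"))
  horizon <- 24
  u <- expand_schedule(it, horizon)
  n_admin <- length(seq(0, horizon * 365.25 / 12 - 1e-9, by = 21))
  expect_equal(sum(u), 2.52 * n_admin, tolerance = 1e-9)
})

test_that("boundary administrations bin into the later cycle", {
  it <- resource_item("b", "control", "PFS", 1,
                      schedule_phase(1, "on-days:30.4375", 0, Inf, "day"))
  u <- expand_schedule(it, 3)
  expect_equal(u, c(0, 1, 0))
})

test_that("listed-day schedules are relative to the phase start", {
  it <- resource_item("l", "control", "PFS", 1,
                      schedule_phase(1, "on-days:0;7;14", phase_start = 2,
                                     phase_end = 3, phase_unit = "month"))
  u <- expand_schedule(it, 4)
  expect_equal(sum(u), 3)
  expect_equal(u[1:2], c(0, 0))  # nothing before the phase window
})

test_that("overlapping phases and time-varying PPS schedules are rejected", {
  bad <- rbind(schedule_phase(1, "per-week", 0, 10, "week"),
               schedule_phase(1, "per-week", 5, 15, "week"))
  it <- resource_item("x", "control", "PFS", 1, bad)
  expect_error(expand_schedule(it, 12), class = "psmforge_invalid_schedule")
  expect_error(
    resource_item("y", "control", "PPS", 1,
                  schedule_phase(1, "per-week", 0, 10, "week")),
    class = "psmforge_invalid_schedule")
})

test_that("cycle costs are linear in unit costs and constant in PPS", {
  items <- list(
    flat_cost_item("a", "intervention", "PFS", 100),
    flat_cost_item("next_line", "intervention", "PPS", 3000),
    flat_cost_item("next_line", "control", "PPS", 3000))
  cc <- cycle_costs(items, 10)
  expect_equal(cc$pps["intervention", ], rep(3000, 10))
  expect_equal(cc$pps["control", ], rep(3000, 10))
  expect_equal(cc$pfs["intervention", ], rep(100, 10))
  expect_equal(cc$pfs["control", ], rep(0, 10))
  items2 <- lapply(items, function(it) { it$unit_cost <- it$unit_cost * 2; it })
  cc2 <- cycle_costs(items2, 10)
  expect_equal(cc2$pfs, cc$pfs * 2)
  expect_equal(cc2$pps, cc$pps * 2)
  # zero-cost items give an all-zero matrix
  items0 <- lapply(items, function(it) { it$unit_cost <- 0; it })
  cc0 <- cycle_costs(items0, 10)
  expect_true(all(cc0$pfs == 0) && all(cc0$pps == 0))
})
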