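# Translation of posology / resource-use schedules into exact per-model-cycle
# unit consumption and costs. One model cycle = one month = 365.25/12 =
# 30.4375 days; a week = 7 days. Administration events falling exactly on a
# cycle boundary belong to the later cycle (half-open binning [start, end)).

DAYS_PER_MONTH <- 365.25 / 12

#' Units per administration for a weight-based dose
#'
#' @param dose_mg_per_kg Dose in mg per kg body weight.
#' @param weight_kg Representative body weight in kg.
#' @param vial_mg Content of one unit (vial) in mg.
#' @param wastage `"none"` (fractional units allowed) or `"round-up-vial"`
#'   (whole vials, ceiling).
#' @return Units consumed per administration.
#' @examples
#' dose_units(3.6, 70, 100)              # 2.52
#' dose_units(3.6, 70, 100, "round-up-vial")  # 3
#' @export
dose_units <- function(dose_mg_per_kg, weight_kg, vial_mg,
                       wastage = c("none", "round-up-vial")) {
  wastage <- match.arg(wastage)
  for (v in c(dose_mg_per_kg, weight_kg, vial_mg)) {
    if (!is.finite(v) || v <= 0) {
      stop_psm("invalid-parameter", "dose, weight and vial size must be positive")
    }
  }
  u <- dose_mg_per_kg * weight_kg / vial_mg
  if (wastage == "round-up-vial") ceiling(u) else u
}

#' Define a resource-consumption schedule
#'
#' A schedule is an ordered list of non-overlapping phases. Each phase gives
#' a quantity (units per administration, or units per period for rate-type
#' frequencies) and a frequency:
#' * rate type: `"per-day"`, `"per-week"`, `"per-month"` — consumption
#'   accrues continuously and is apportioned to model cycles by exact
#'   day-count;
#' * event type: `"every-<k>-weeks"` — administrations at the phase start and
#'   every `7k` days thereafter while inside the phase window;
#'   `"on-days:d1;d2;..."` — administrations on listed days counted from the
#'   phase start (day 0 = phase start).
#'
#' Phase windows are `[start, end)` in the unit given by `phase_unit`
#' (`"day"`, `"week"`, `"month"`, or `"txcycle"` — treatment cycles of
#' `txcycle_length_weeks` weeks, counted from model start). `end = Inf` (or
#' `NA`) means "until the model horizon". An optional `cap` limits
#' administrations to treatment cycles `1..cap` counted from model start.
#'
#' @param quantity Units per administration (event type) or per period (rate
#'   type); non-negative.
#' @param unit Frequency string as above.
#' @param phase_start,phase_end Window bounds in `phase_unit` units.
#' @param phase_unit `"day"`, `"week"`, `"month"` or `"txcycle"`.
#' @param txcycle_length_weeks Length of one treatment cycle in weeks
#'   (required when `phase_unit = "txcycle"` or `cap` is set).
#' @param cap Optional maximum number of treatment cycles (from model start)
#'   during which administrations may occur.
#' @return A one-row data frame (phase); combine phases with `rbind`.
#' @export
schedule_phase <- function(quantity, unit, phase_start = 0, phase_end = Inf,
                           phase_unit = "month", txcycle_length_weeks = NA,
                           cap = NA) {
  if (!is.finite(quantity) || quantity < 0) {
    stop_psm("invalid-parameter", "schedule quantity must be >= 0")
  }
  data.frame(quantity = quantity, unit = unit, phase_start = phase_start,
             phase_end = phase_end, phase_unit = phase_unit,
             txcycle_length_weeks = txcycle_length_weeks, cap = cap,
             stringsAsFactors = FALSE)
}

#' Define a resource item
#'
#' @param name Resource name (matches a row of the costs table).
#' @param arm `"intervention"` or `"control"`.
#' @param state `"PFS"` or `"PPS"`. Post-progression consumption cannot vary
#'   over time: PPS items must have a single rate-type phase covering the
#'   whole horizon.
#' @param unit_cost Cost per unit, `>= 0`.
#' @param schedule Data frame of phases from [schedule_phase()].
#' @return An object of class `resource_item`.
#' @export
resource_item <- function(name, arm, state, unit_cost, schedule) {
  if (!state %in% c("PFS", "PPS")) stop_psm("invalid-parameter", "state must be PFS or PPS")
  if (!is.finite(unit_cost) || unit_cost < 0) {
    stop_psm("invalid-parameter", sprintf("unit cost for '%s' must be >= 0", name))
  }
  if (state == "PPS") {
    rate_units <- c("per-day", "per-week", "per-month")
    if (nrow(schedule) != 1 || !schedule$unit %in% rate_units ||
        schedule$phase_start != 0 || !is.infinite(schedule$phase_end)) {
      stop_psm("invalid-schedule",
               sprintf("PPS item '%s': consumption cannot vary over time (one unbounded rate-type phase)", name))
    }
  }
  structure(list(name = name, arm = arm, state = state,
                 unit_cost = unit_cost, schedule = schedule),
            class = "resource_item")
}

# window bounds in days from model start
.phase_days <- function(ph) {
  mult <- switch(ph$phase_unit,
                 day = 1, week = 7, month = DAYS_PER_MONTH,
                 txcycle = {
                   if (!is.finite(ph$txcycle_length_weeks)) {
                     stop_psm("invalid-schedule", "txcycle phase needs txcycle_length_weeks")
                   }
                   7 * ph$txcycle_length_weeks
                 },
                 stop_psm("invalid-schedule",
                          sprintf("unknown phase unit '%s'", ph$phase_unit)))
  end <- if (is.na(ph$phase_end)) Inf else ph$phase_end
  c(ph$phase_start * mult, end * mult)
}

#' Expand a resource item to per-model-cycle unit consumption
#'
#' Administration events are placed on a day timeline from the schedule
#' grammar and binned into monthly cycles (`[start, end)`, boundary events to
#' the later cycle); rate-type phases apportion by exact day counts.
#'
#' @param item A [resource_item()].
#' @param horizon_months Number of monthly model cycles.
#' @return Numeric vector of length `horizon_months`: units consumed in each
#'   cycle (conditional on state membership; occupancy weighting happens in
#'   the engine).
#' @export
expand_schedule <- function(item, horizon_months) {
  horizon_months <- as.integer(horizon_months)
  if (horizon_months < 1) stop_psm("invalid-parameter", "horizon must be >= 1")
  sch <- item$schedule
  # validate non-overlap on the day timeline
  if (nrow(sch) > 1) {
    wins <- t(vapply(seq_len(nrow(sch)), function(i) .phase_days(sch[i, ]), numeric(2)))
    ord <- order(wins[, 1])
    wins <- wins[ord, , drop = FALSE]
    if (any(wins[-nrow(wins), 2] > wins[-1, 1] + 1e-9)) {
      stop_psm("invalid-schedule",
               sprintf("overlapping phases in schedule for '%s'", item$name))
    }
  }
  horizon_days <- horizon_months * DAYS_PER_MONTH
  units <- numeric(horizon_months)
  cyc_start <- (seq_len(horizon_months) - 1) * DAYS_PER_MONTH
  cyc_end <- seq_len(horizon_months) * DAYS_PER_MONTH

  for (i in seq_len(nrow(sch))) {
    ph <- sch[i, ]
    win <- .phase_days(ph)
    lo <- max(win[1], 0); hi <- min(win[2], horizon_days)
    cap_day <- Inf
    if (is.finite(ph$cap)) {
      if (!is.finite(ph$txcycle_length_weeks)) {
        stop_psm("invalid-schedule", "cap in treatment cycles needs txcycle_length_weeks")
      }
      cap_day <- ph$cap * 7 * ph$txcycle_length_weeks
    }
    if (ph$unit %in% c("per-day", "per-week", "per-month")) {
      per_day <- ph$quantity / switch(ph$unit, "per-day" = 1, "per-week" = 7,
                                      "per-month" = DAYS_PER_MONTH)
      hi2 <- min(hi, cap_day)
      if (hi2 > lo) {
        overlap <- pmax(0, pmin(cyc_end, hi2) - pmax(cyc_start, lo))
        units <- units + per_day * overlap
      }
    } else if (grepl("^every-[0-9]+-weeks$", ph$unit)) {
      k <- as.numeric(sub("^every-([0-9]+)-weeks$", "\\1", ph$unit))
      upper <- min(win[2], horizon_days, cap_day)
      if (win[1] >= upper) next
      step <- 7 * k
      days <- win[1] + (0:ceiling((upper - win[1]) / step)) * step
      days <- days[days >= 0 & days < upper - 1e-9]  # window is half-open
      units <- .bin_events(units, days, ph$quantity)
    } else if (grepl("^on-days:", ph$unit)) {
      offs <- as.numeric(strsplit(sub("^on-days:", "", ph$unit), ";")[[1]])
      if (any(!is.finite(offs)) || any(offs < 0)) {
        stop_psm("invalid-schedule", sprintf("bad day list in '%s'", ph$unit))
      }
      days <- win[1] + offs
      days <- days[days >= 0 & days < min(win[2], horizon_days, cap_day)]
      units <- .bin_events(units, days, ph$quantity)
    } else {
      stop_psm("invalid-schedule",
               sprintf("unknown frequency unit '%s' for '%s'", ph$unit, item$name))
    }
  }
  units
}

.bin_events <- function(units, days, quantity) {
  if (length(days) == 0) return(units)
  cyc <- floor(days / DAYS_PER_MONTH) + 1  # boundary day -> later cycle
  cyc <- cyc[cyc >= 1 & cyc <= length(units)]
  for (cc in cyc) units[cc] <- units[cc] + quantity
  units
}

#' Per-cycle cost matrices for a set of resource items
#'
#' @param items List of [resource_item()]s.
#' @param horizon_months Number of monthly cycles.
#' @return A list with elements `pfs` and `pps`, each a matrix with rows
#'   `intervention`/`control` and `horizon_months` columns giving the cost
#'   accrued per cycle conditional on full state membership.
#' @export
cycle_costs <- function(items, horizon_months) {
  arms <- c("intervention", "control")
  mk <- function() matrix(0, nrow = 2, ncol = horizon_months,
                          dimnames = list(arms, NULL))
  out <- list(pfs = mk(), pps = mk())
  for (it in items) {
    if (!it$arm %in% arms) {
      stop_psm("invalid-parameter", sprintf("unknown arm '%s' for '%s'", it$arm, it$name))
    }
    slot <- if (it$state == "PFS") "pfs" else "pps"
    out[[slot]][it$arm, ] <- out[[slot]][it$arm, ] +
      it$unit_cost * expand_schedule(it, horizon_months)
  }
  out
}
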