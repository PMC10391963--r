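# Synthetic-trial generator. Produces ground-truth IPD, digitized curves,
# risk tables and complete input templates so every pipeline stage is
# testable without external data. This is a QA device: progression-free
# time is coupled to death time as PFS = min(OS, independent progression
# time), which guarantees per-subject PFS <= OS (the partitioned-survival
# ordering assumption) while matching the marginal families approximately.

#' Specify a synthetic two-arm trial
#'
#' Control-arm event times are drawn from the stated families; the
#' intervention arm is drawn under the same constant-hazard-ratio rule the
#' engine uses (`S_int = S_ctrl^hr`, per endpoint). Defaults emulate a
#' trial of the shape the package's worked example models: a moderately
#' effective second-line oncology intervention (strong PFS effect, smaller
#' OS effect) with about 30 months of follow-up and ~260 subjects per arm.
#'
#' @param os_family,os_params Control-arm overall-survival family/parameters.
#' @param prog_family,prog_params Family/parameters of the latent
#'   progression time (PFS = min(progression, OS)).
#' @param hr_os,hr_pfs True hazard ratios (> 0) applied to OS and to the
#'   progression component.
#' @param n_per_arm Subjects per arm (>= 10).
#' @param censor_months Administrative censoring (end of follow-up), months.
#' @param seed RNG seed; every simulation from this spec is deterministic.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(os_family = "weibull",
                       os_params = c(shape = 1.3, scale = 45),
                       prog_family = "weibull",
                       prog_params = c(shape = 1.1, scale = 10),
                       hr_os = 0.55, hr_pfs = 0.28,
                       n_per_arm = 260, censor_months = 30, seed = 1) {
  if (n_per_arm < 10) stop_psm("invalid-parameter", "n_per_arm must be >= 10")
  for (h in c(hr_os, hr_pfs)) {
    if (!is.finite(h) || h <= 0) stop_psm("invalid-parameter", "hazard ratios must be > 0")
  }
  if (!is.finite(censor_months) || censor_months <= 0) {
    stop_psm("invalid-parameter", "censor_months must be > 0")
  }
  .check_params(os_family, as.list(os_params))
  .check_params(prog_family, as.list(prog_params))
  structure(list(os_family = os_family, os_params = as.list(os_params),
                 prog_family = prog_family, prog_params = as.list(prog_params),
                 hr_os = hr_os, hr_pfs = hr_pfs, n_per_arm = n_per_arm,
                 censor_months = censor_months, seed = seed),
            class = "trial_spec")
}

# inverse-survival draw under an HR: S^hr, so S^{-1}(u^{1/hr}) at u ~ U(0,1)
.rsurv_hr <- function(n, family, params, hr) {
  u <- stats::runif(n)
  psm_qsurv(family, unlist(params), pmin(u^(1 / hr), 1))
}

#' Simulate a two-arm trial with OS and PFS endpoints
#'
#' @param spec A [trial_spec()].
#' @return List with `ipd` (named list `os_intervention`, `os_control`,
#'   `pfs_intervention`, `pfs_control` of [psm_ipd()]) and `truth` (the spec
#'   plus observed event counts).
#' @export
simulate_trial <- function(spec) {
  set.seed(spec$seed)
  out <- list()
  counts <- list()
  for (arm in c("intervention", "control")) {
    hr_os <- if (arm == "intervention") spec$hr_os else 1
    hr_pfs <- if (arm == "intervention") spec$hr_pfs else 1
    t_os <- .rsurv_hr(spec$n_per_arm, spec$os_family, spec$os_params, hr_os)
    t_prog <- .rsurv_hr(spec$n_per_arm, spec$prog_family, spec$prog_params, hr_pfs)
    t_pfs <- pmin(t_os, t_prog)
    cens <- spec$censor_months
    mk <- function(tt) {
      obs <- pmin(tt, cens)
      obs[obs <= 0] <- 1e-6
      psm_ipd(obs, as.integer(tt <= cens), arm = arm)
    }
    os_ipd <- mk(t_os); os_ipd$endpoint <- "OS"
    pfs_ipd <- mk(t_pfs); pfs_ipd$endpoint <- "PFS"
    out[[paste0("os_", arm)]] <- os_ipd
    out[[paste0("pfs_", arm)]] <- pfs_ipd
    counts[[arm]] <- c(os_events = sum(os_ipd$event), pfs_events = sum(pfs_ipd$event))
  }
  list(ipd = out, truth = c(unclass(spec), list(event_counts = counts)))
}

#' Digitize an IPD set: sample its KM curve on a monthly grid
#'
#' Emulates what a user extracts from a published plot: KM probabilities at
#' grid times, numbers at risk at the reporting times and (optionally) the
#' total event count.
#'
#' @param ipd A [psm_ipd()].
#' @param grid Monthly coordinate times (must start at 0 and lie within
#'   follow-up).
#' @param risk_times Times at which numbers at risk are reported (subset of
#'   `grid`).
#' @param with_events Include the total event count?
#' @return A [digitized_curve()].
#' @export
digitize <- function(ipd, grid = NULL, risk_times = NULL, with_events = FALSE) {
  if (is.null(grid)) grid <- 0:ceiling(max(ipd$time))
  if (is.null(risk_times)) risk_times <- grid[grid %% 6 == 0]
  km <- km_curve(ipd)
  probs <- km$S(grid)
  n_at_risk <- vapply(risk_times, function(t) sum(ipd$time >= t), numeric(1))
  # printed risk tables never rise; enforce in case of exact-tie boundary effects
  n_at_risk <- cummin(n_at_risk)
  digitized_curve(ipd$endpoint[1], ipd$arm[1], grid, probs, risk_times,
                  n_at_risk,
                  total_events = if (with_events) sum(ipd$event) else NULL)
}

#' Default economic parameters for generated templates
#'
#' A stylised second-line oncology costing: a weight-based intervention drug
#' given every 3 weeks during PFS in the intervention arm, a comparator drug
#' likewise in the control arm, and a `next_line` monthly cost after
#' progression (zero in the base case, analysed in DSA). All utilities 1
#' (life-year mode).
#'
#' @return Named list understood by [make_template()].
#' @export
default_econ_params <- function() {
  list(
    discount_rate = 0.03,
    drugs = list(
      list(name = "drug_intervention", arm = "intervention",
           units_per_admin = dose_units(5.4, 70, 100), every_weeks = 3,
           unit_cost = 2194, dsa_low = 1097, dsa_high = 2194),
      list(name = "drug_control", arm = "control",
           units_per_admin = dose_units(3.6, 70, 100), every_weeks = 3,
           unit_cost = 2720, dsa_low = 1360, dsa_high = 2720)),
    next_line_cost = 0, next_line_dsa = c(0, 3000),
    utilities = c(u_pfs_intervention = 1, u_pfs_control = 1, u_pps = 1),
    dsa = list(discount_rate = c(0, 0.05)))
}

#' Write a complete, readable input template for a synthetic trial
#'
#' Simulates the trial, digitizes all four curves and writes the full CSV
#' template bundle plus a `truth.json` sidecar with the generating
#' parameters and seed.
#'
#' @param spec A [trial_spec()].
#' @param econ Economic parameters, see [default_econ_params()].
#' @param dir Output directory (created).
#' @param hr_mode `"truth"` writes the spec's true hazard ratios into the
#'   template; `"estimate"` writes the sentinel so the pipeline estimates
#'   them by Cox regression.
#' @return `dir`, invisibly.
#' @export
make_template <- function(spec, econ = default_econ_params(), dir,
                          hr_mode = c("truth", "estimate")) {
  hr_mode <- match.arg(hr_mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_trial(spec)
  grid <- 0:floor(spec$censor_months)
  risk_times <- grid[grid %% 6 == 0]
  curves <- lapply(sim$ipd, digitize, grid = grid, risk_times = risk_times,
                   with_events = TRUE)

  sp <- data.frame(time = grid)
  nr <- data.frame(time = grid)
  for (nm in names(curves)) {
    key <- sub("^(os|pfs)_", "\\1_", nm)
    sp[[key]] <- curves[[nm]]$surv_probs
    col <- rep(NA_integer_, length(grid))
    col[match(curves[[nm]]$risk_times, grid)] <- curves[[nm]]$n_at_risk
    nr[[key]] <- col
  }
  utils::write.csv(sp, file.path(dir, "surv_probs.csv"), row.names = FALSE)
  utils::write.csv(nr, file.path(dir, "n_at_risk.csv"), row.names = FALSE)

  ev <- do.call(rbind, lapply(names(curves), function(nm) {
    data.frame(endpoint = curves[[nm]]$endpoint, arm = curves[[nm]]$arm,
               events = curves[[nm]]$total_events)
  }))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)

  hr_vals <- if (hr_mode == "truth") c(spec$hr_os, spec$hr_pfs) else
    c("estimate", "estimate")
  utils::write.csv(data.frame(endpoint = c("OS", "PFS"), value = hr_vals),
                   file.path(dir, "hr.csv"), row.names = FALSE)
  utils::write.csv(data.frame(annual_rate = econ$discount_rate),
                   file.path(dir, "discount.csv"), row.names = FALSE)

  costs <- do.call(rbind, lapply(econ$drugs, function(d) {
    data.frame(name = d$name, unit_cost = d$unit_cost,
               dsa_low = d$dsa_low, dsa_high = d$dsa_high)
  }))
  costs <- rbind(costs, data.frame(name = "next_line",
                                   unit_cost = econ$next_line_cost,
                                   dsa_low = econ$next_line_dsa[1],
                                   dsa_high = econ$next_line_dsa[2]))
  utils::write.csv(costs, file.path(dir, "costs.csv"), row.names = FALSE)

  rpfs <- do.call(rbind, lapply(econ$drugs, function(d) {
    data.frame(name = d$name, arm = d$arm, quantity = d$units_per_admin,
               unit = sprintf("every-%d-weeks", d$every_weeks),
               phase_start = 0, phase_end = NA, phase_unit = "week",
               txcycle_length_weeks = NA, cap = NA)
  }))
  utils::write.csv(rpfs, file.path(dir, "resources_pfs.csv"), row.names = FALSE)
  rpps <- data.frame(name = "next_line", arm = c("intervention", "control"),
                     quantity = 1, unit = "per-month")
  utils::write.csv(rpps, file.path(dir, "resources_pps.csv"), row.names = FALSE)

  utils::write.csv(data.frame(parameter = names(econ$utilities),
                              value = unname(econ$utilities)),
                   file.path(dir, "utilities.csv"), row.names = FALSE)

  dsa_rows <- data.frame(parameter = character(), low = numeric(),
                         high = numeric())
  if (hr_mode == "truth") {
    dsa_rows <- rbind(dsa_rows,
                      data.frame(parameter = c("hr_os", "hr_pfs"),
                                 low = c(spec$hr_os * 0.7, spec$hr_pfs * 0.7),
                                 high = pmin(c(spec$hr_os * 1.3, spec$hr_pfs * 1.3), 1)))
  }
  for (nm in names(econ$dsa)) {
    dsa_rows <- rbind(dsa_rows, data.frame(parameter = nm, low = econ$dsa[[nm]][1],
                                           high = econ$dsa[[nm]][2]))
  }
  utils::write.csv(dsa_rows, file.path(dir, "dsa.csv"), row.names = FALSE)

  writeLines(jsonlite::toJSON(c(unclass(spec), list(hr_mode = hr_mode)),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(dir, "truth.json"))
  invisible(dir)
}
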