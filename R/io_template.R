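# Tabular input template. A template is either a directory of CSV files or
# a single XLSX workbook (sheet access via readxl when installed) with the
# fixed sheet names: surv_probs, n_at_risk, events (optional), hr, discount,
# costs, resources_pfs, resources_pps, utilities, dsa (optional). Numbers
# use dot-decimal, no thousands separators.

.TEMPLATE_SHEETS <- c("surv_probs", "n_at_risk", "hr", "discount", "costs",
                      "resources_pfs", "resources_pps", "utilities")
.CURVE_COLS <- c("os_intervention", "os_control", "pfs_intervention", "pfs_control")

#' Assemble and validate model inputs
#'
#' Usually produced by [read_template()]; exposed so programmatic callers
#' (and the synthetic-trial generator) can build inputs directly.
#'
#' @param curves Named list of four [digitized_curve()]s with names
#'   `os_intervention`, `os_control`, `pfs_intervention`, `pfs_control`.
#' @param hr_os,hr_pfs Positive hazard ratio, or the string `"estimate"` to
#'   request Cox estimation from the reconstructed IPD.
#' @param annual_discount_rate Annual discount rate in `[0, 1)`.
#' @param horizon_months Model horizon in monthly cycles, `>= 1`.
#' @param utilities Named list: `u_pfs_intervention`, `u_pfs_control`
#'   (per-arm progression-free utilities) and `u_pps` (single
#'   post-progression utility), each in `[0, 1]`. All equal to 1 switches
#'   the model to life-years mode.
#' @param resources List of [resource_item()]s.
#' @param dsa_ranges Named list of `c(low, high)` ranges; names are
#'   `hr_os`, `hr_pfs`, `discount_rate`, `u_pfs_intervention`,
#'   `u_pfs_control`, `u_pps` or `cost:<resource name>`.
#' @param dist_pfs,dist_os Parametric family chosen for each endpoint.
#' @return An object of class `psm_inputs`.
#' @export
model_inputs <- function(curves, hr_os, hr_pfs, annual_discount_rate,
                         horizon_months, utilities, resources,
                         dsa_ranges = list(), dist_pfs = "weibull",
                         dist_os = "weibull") {
  if (!setequal(names(curves), .CURVE_COLS)) {
    stop_psm("template-incomplete",
             sprintf("need exactly four curves named %s",
                     paste(.CURVE_COLS, collapse = ", ")))
  }
  for (nm in .CURVE_COLS) {
    if (!inherits(curves[[nm]], "digitized_curve")) {
      stop_psm("invalid-curve", sprintf("curve '%s' is not a digitized_curve", nm))
    }
  }
  for (h in list(hr_os = hr_os, hr_pfs = hr_pfs)) {
    if (!(identical(h, "estimate") || (is.numeric(h) && is.finite(h) && h > 0))) {
      stop_psm("invalid-parameter", "hazard ratios must be positive numbers or \"estimate\"")
    }
  }
  if (!is.finite(annual_discount_rate) || annual_discount_rate < 0 ||
      annual_discount_rate >= 1) {
    stop_psm("invalid-parameter", "annual discount rate must be in [0, 1)")
  }
  horizon_months <- as.integer(horizon_months)
  if (is.na(horizon_months) || horizon_months < 1) {
    stop_psm("invalid-parameter", "horizon must be a positive integer")
  }
  need_u <- c("u_pfs_intervention", "u_pfs_control", "u_pps")
  if (!all(need_u %in% names(utilities))) {
    stop_psm("template-incomplete",
             sprintf("utilities must provide %s", paste(need_u, collapse = ", ")))
  }
  for (nm in need_u) {
    u <- utilities[[nm]]
    if (!is.finite(u) || u < 0 || u > 1) {
      stop_psm("invalid-parameter",
               sprintf("utility '%s' must lie in [0, 1] (got %s)", nm, format(u)))
    }
  }
  .get_family(dist_pfs); .get_family(dist_os)
  out <- structure(list(
    curves = curves[.CURVE_COLS], hr_os = hr_os, hr_pfs = hr_pfs,
    annual_discount_rate = annual_discount_rate,
    horizon_months = horizon_months,
    utilities = utilities[need_u], resources = resources,
    dsa_ranges = dsa_ranges, dist_pfs = dist_pfs, dist_os = dist_os,
    ly_mode = all(unlist(utilities[need_u]) == 1)), class = "psm_inputs")
  .check_dsa_ranges(out)
  out
}

.dsa_base_value <- function(inputs, param) {
  if (param == "hr_os") return(if (identical(inputs$hr_os, "estimate")) NA_real_ else inputs$hr_os)
  if (param == "hr_pfs") return(if (identical(inputs$hr_pfs, "estimate")) NA_real_ else inputs$hr_pfs)
  if (param == "discount_rate") return(inputs$annual_discount_rate)
  if (param %in% names(inputs$utilities)) return(inputs$utilities[[param]])
  if (startsWith(param, "cost:")) {
    nm <- sub("^cost:", "", param)
    for (it in inputs$resources) if (it$name == nm) return(it$unit_cost)
    return(NA_real_)
  }
  NA_real_
}

.check_dsa_ranges <- function(inputs) {
  for (param in names(inputs$dsa_ranges)) {
    rg <- inputs$dsa_ranges[[param]]
    base <- .dsa_base_value(inputs, param)
    if (is.na(base)) {
      stop_psm("invalid-range",
               sprintf("dsa: parameter '%s' has no base value in the template", param))
    }
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2] ||
        rg[1] > base + 1e-12 || rg[2] < base - 1e-12) {
      stop_psm("invalid-range",
               sprintf("dsa: range [%s, %s] for '%s' must bracket the base value %s",
                       format(rg[1]), format(rg[2]), param, format(base)))
    }
  }
  invisible(inputs)
}

#' @export
print.psm_inputs <- function(x, ...) {
  cat(sprintf("<psm_inputs> horizon %d months, discount %.3f, %s mode\n",
              x$horizon_months, x$annual_discount_rate,
              if (x$ly_mode) "life-year" else "QALY"))
  cat(sprintf("  HR: OS %s, PFS %s; families: PFS %s, OS %s; %d resource items\n",
              format(x$hr_os), format(x$hr_pfs), x$dist_pfs, x$dist_os,
              length(x$resources)))
  invisible(x)
}

# -- sheet access ------------------------------------------------------------

.template_reader <- function(path) {
  if (dir.exists(path)) {
    list(
      has = function(sheet) file.exists(file.path(path, paste0(sheet, ".csv"))),
      get = function(sheet) utils::read.csv(file.path(path, paste0(sheet, ".csv")),
                                            stringsAsFactors = FALSE))
  } else if (file.exists(path) && grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_psm("template-incomplete",
               "reading .xlsx templates requires the 'readxl' package; supply a CSV directory instead")
    }
    sheets <- readxl::excel_sheets(path)
    list(
      has = function(sheet) sheet %in% sheets,
      get = function(sheet) as.data.frame(readxl::read_xlsx(path, sheet = sheet)))
  } else {
    stop_psm("template-incomplete",
             sprintf("template path '%s' is neither a directory of CSVs nor an .xlsx file", path))
  }
}

.require_cols <- function(d, cols, sheet) {
  miss <- setdiff(cols, names(d))
  if (length(miss)) {
    stop_psm("template-incomplete",
             sprintf("sheet '%s': missing column(s) %s", sheet,
                     paste(miss, collapse = ", ")))
  }
  d
}

#' Read an input template
#'
#' Reads and validates the full model-input bundle. Every validation failure
#' names the offending sheet and rule. Horizon and the parametric families
#' are run-time choices, not template data, and are supplied as arguments.
#'
#' @param path Directory of CSV files or an `.xlsx` workbook.
#' @param horizon_months Model horizon in monthly cycles.
#' @param dist_pfs,dist_os Parametric family for each endpoint.
#' @return A validated `psm_inputs` object.
#' @export
read_template <- function(path, horizon_months = 100,
                          dist_pfs = "weibull", dist_os = "weibull") {
  rd <- .template_reader(path)
  for (sheet in .TEMPLATE_SHEETS) {
    if (!rd$has(sheet)) {
      stop_psm("template-incomplete", sprintf("required sheet '%s' is missing", sheet))
    }
  }

  sp <- .require_cols(rd$get("surv_probs"), c("time", .CURVE_COLS), "surv_probs")
  nr <- .require_cols(rd$get("n_at_risk"), c("time", .CURVE_COLS), "n_at_risk")
  events <- if (rd$has("events")) {
    .require_cols(rd$get("events"), c("endpoint", "arm", "events"), "events")
  } else NULL

  curves <- list()
  for (col in .CURVE_COLS) {
    ok <- !is.na(sp[[col]])
    rt_ok <- !is.na(nr[[col]])
    endpoint <- toupper(sub("_.*$", "", col))
    arm <- sub("^.*_", "", col)
    tot <- NULL
    if (!is.null(events)) {
      row <- events[toupper(events$endpoint) == endpoint & events$arm == arm, ]
      if (nrow(row) == 1 && !is.na(row$events)) tot <- row$events
    }
    curves[[col]] <- withCallingHandlers(
      tryCatch(
        digitized_curve(endpoint, arm, sp$time[ok], sp[[col]][ok],
                        nr$time[rt_ok], nr[[col]][rt_ok], total_events = tot),
        error = function(e) {
          if (inherits(e, "psmforge_error")) {
            stop_psm(psm_error_code(e),
                     sprintf("sheet 'surv_probs'/'n_at_risk', column '%s': %s",
                             col, conditionMessage(e)))
          }
          stop(e)
        }),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  hr <- .require_cols(rd$get("hr"), c("endpoint", "value"), "hr")
  get_hr <- function(ep) {
    row <- hr[toupper(hr$endpoint) == ep, ]
    if (nrow(row) != 1) {
      stop_psm("template-incomplete", sprintf("sheet 'hr': need one row for endpoint %s", ep))
    }
    v <- row$value
    if (identical(tolower(as.character(v)), "estimate")) return("estimate")
    v <- suppressWarnings(as.numeric(v))
    if (!is.finite(v) || v <= 0) {
      stop_psm("invalid-parameter",
               sprintf("sheet 'hr', endpoint %s: value must be positive or \"estimate\"", ep))
    }
    v
  }

  disc <- .require_cols(rd$get("discount"), "annual_rate", "discount")
  rate <- suppressWarnings(as.numeric(disc$annual_rate[1]))
  if (!is.finite(rate)) {
    stop_psm("invalid-parameter", "sheet 'discount': annual_rate must be numeric")
  }

  costs <- .require_cols(rd$get("costs"), c("name", "unit_cost"), "costs")
  cost_of <- function(nm) {
    row <- costs[costs$name == nm, ]
    if (nrow(row) != 1) {
      stop_psm("template-incomplete",
               sprintf("sheet 'costs': resource '%s' needs exactly one unit-cost row", nm))
    }
    v <- suppressWarnings(as.numeric(row$unit_cost))
    if (!is.finite(v) || v < 0) {
      stop_psm("invalid-parameter",
               sprintf("sheet 'costs', resource '%s': unit cost must be >= 0", nm))
    }
    v
  }

  rpfs <- .require_cols(rd$get("resources_pfs"),
                        c("name", "arm", "quantity", "unit", "phase_start",
                          "phase_end", "phase_unit", "txcycle_length_weeks", "cap"),
                        "resources_pfs")
  rpps <- .require_cols(rd$get("resources_pps"),
                        c("name", "arm", "quantity", "unit"), "resources_pps")

  items <- list()
  if (nrow(rpfs)) {
    for (key in unique(paste(rpfs$name, rpfs$arm, sep = "\r"))) {
      parts <- strsplit(key, "\r")[[1]]
      rows <- rpfs[rpfs$name == parts[1] & rpfs$arm == parts[2], ]
      phases <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        r <- rows[i, ]
        schedule_phase(r$quantity, r$unit, r$phase_start,
                       ifelse(is.na(r$phase_end), Inf, r$phase_end),
                       r$phase_unit, r$txcycle_length_weeks, r$cap)
      }))
      items[[length(items) + 1]] <-
        resource_item(parts[1], parts[2], "PFS", cost_of(parts[1]), phases)
    }
  }
  if (nrow(rpps)) {
    for (i in seq_len(nrow(rpps))) {
      r <- rpps[i, ]
      items[[length(items) + 1]] <-
        resource_item(r$name, r$arm, "PPS", cost_of(r$name),
                      schedule_phase(r$quantity, r$unit))
    }
  }

  ut <- .require_cols(rd$get("utilities"), c("parameter", "value"), "utilities")
  utilities <- list()
  for (nm in c("u_pfs_intervention", "u_pfs_control", "u_pps")) {
    row <- ut[ut$parameter == nm, ]
    if (nrow(row) != 1) {
      stop_psm("template-incomplete", sprintf("sheet 'utilities': need one row '%s'", nm))
    }
    utilities[[nm]] <- suppressWarnings(as.numeric(row$value))
  }

  dsa_ranges <- list()
  if (rd$has("dsa")) {
    dsa <- .require_cols(rd$get("dsa"), c("parameter", "low", "high"), "dsa")
    for (i in seq_len(nrow(dsa))) {
      dsa_ranges[[dsa$parameter[i]]] <- c(as.numeric(dsa$low[i]),
                                          as.numeric(dsa$high[i]))
    }
  }
  if (all(c("dsa_low", "dsa_high") %in% names(costs))) {
    for (i in seq_len(nrow(costs))) {
      lo <- suppressWarnings(as.numeric(costs$dsa_low[i]))
      hi <- suppressWarnings(as.numeric(costs$dsa_high[i]))
      if (is.finite(lo) && is.finite(hi)) {
        dsa_ranges[[paste0("cost:", costs$name[i])]] <- c(lo, hi)
      }
    }
  }

  model_inputs(curves, get_hr("OS"), get_hr("PFS"), rate, horizon_months,
               utilities, items, dsa_ranges, dist_pfs, dist_os)
}

#' Write the result tables
#'
#' Emits three CSVs into `out_dir`: `results.csv` (undiscounted and
#' discounted totals per arm, increments and ICER; an undefined ICER is
#' rendered as the string `"undefined"`), `trace.csv` (per-arm per-cycle
#' state occupancy, costs and (Q)ALYs) and, when a DSA result is supplied,
#' `dsa.csv` (tornado-ordered scenario table; scenarios that hit the engine's
#' OS-below-PFS guard are flagged `"engine-failure"`).
#'
#' @param results A `psm_results` from [run_psm()].
#' @param dsa Optional `dsa_result` from [run_dsa()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(results, dsa = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  s <- results$summary
  fmt_icer <- function(v, status) {
    if (is.na(v)) "undefined" else as.character(v)
  }
  res <- data.frame(
    quantity = c("cost", "cost_disc", "ly", "ly_disc", "qaly", "qaly_disc"),
    intervention = unlist(s$per_arm$intervention),
    control = unlist(s$per_arm$control),
    incremental = unlist(s$incremental),
    stringsAsFactors = FALSE)
  extra <- data.frame(
    quantity = c("icer_discounted", "icer_status", "icer_undiscounted",
                 "icer_undiscounted_status"),
    intervention = NA, control = NA,
    incremental = c(fmt_icer(s$icer, s$icer_status), s$icer_status,
                    fmt_icer(s$icer_undiscounted, s$icer_undiscounted_status),
                    s$icer_undiscounted_status),
    stringsAsFactors = FALSE)
  paths <- character()
  p <- file.path(out_dir, "results.csv")
  utils::write.csv(rbind(res, extra), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "trace.csv")
  utils::write.csv(results$trace, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(dsa)) {
    p <- file.path(out_dir, "dsa.csv")
    utils::write.csv(tornado_order(dsa), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
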