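# Univariate (one-at-a-time) deterministic sensitivity analysis. Each
# analysable parameter is set to its low and high bound with everything else
# held at base; engine failures inside a scenario (the OS-below-PFS guard)
# are caught and recorded, never fatal to the sweep.

.apply_scenario <- function(inputs, param, value) {
  if (param == "hr_os") inputs$hr_os <- value
  else if (param == "hr_pfs") inputs$hr_pfs <- value
  else if (param == "discount_rate") inputs$annual_discount_rate <- value
  else if (param %in% names(inputs$utilities)) {
    inputs$utilities[[param]] <- value
    inputs$ly_mode <- all(unlist(inputs$utilities) == 1)
  } else if (startsWith(param, "cost:")) {
    nm <- sub("^cost:", "", param)
    hit <- FALSE
    for (i in seq_along(inputs$resources)) {
      if (inputs$resources[[i]]$name == nm) {
        inputs$resources[[i]]$unit_cost <- value
        hit <- TRUE
      }
    }
    if (!hit) stop_psm("invalid-range", sprintf("dsa: unknown resource '%s'", nm))
  } else {
    stop_psm("invalid-range", sprintf("dsa: unknown parameter '%s'", param))
  }
  inputs
}

.run_scenario <- function(inputs, pfs_model, os_model, correction) {
  tryCatch({
    r <- run_psm(inputs, pfs_model, os_model, correction)
    s <- r$summary
    list(status = if (is.na(s$icer)) "icer-undefined" else "ok",
         icer = s$icer, inc_cost = s$incremental$cost_disc,
         inc_qaly = s$incremental$qaly_disc)
  }, psmforge_logical_inconsistency = function(e) {
    list(status = "engine-failure", icer = NA_real_,
         inc_cost = NA_real_, inc_qaly = NA_real_)
  })
}

#' Run the univariate sensitivity analysis
#'
#' Sweeps every parameter with a range in `inputs$dsa_ranges` (hazard
#' ratios, discount rate, unit costs, utilities; resource-use quantities are
#' not analysable). Hazard ratios must already be resolved to numbers (see
#' [run_pipeline()]).
#'
#' @inheritParams run_psm
#' @return An object of class `dsa_result`: a data frame with one row per
#'   parameter (`parameter`, `base`, `low`, `high`, `icer_low`, `icer_high`,
#'   `inc_cost_low/high`, `inc_qaly_low/high`, `status_low`, `status_high`)
#'   plus the base-case summary as attribute `"base"`.
#' @export
run_dsa <- function(inputs, pfs_model, os_model,
                    correction = c("trapezoid", "midpoint")) {
  correction <- match.arg(correction)
  if (identical(inputs$hr_os, "estimate") || identical(inputs$hr_pfs, "estimate")) {
    stop_psm("invalid-parameter",
             "resolve hazard ratios (run_pipeline) before the sensitivity analysis")
  }
  base_run <- run_psm(inputs, pfs_model, os_model, correction)
  params <- names(inputs$dsa_ranges)
  rows <- lapply(params, function(pm) {
    rg <- inputs$dsa_ranges[[pm]]
    base <- .dsa_base_value(inputs, pm)
    lo <- .run_scenario(.apply_scenario(inputs, pm, rg[1]), pfs_model, os_model, correction)
    hi <- .run_scenario(.apply_scenario(inputs, pm, rg[2]), pfs_model, os_model, correction)
    data.frame(parameter = pm, base = base, low = rg[1], high = rg[2],
               icer_low = lo$icer, icer_high = hi$icer,
               inc_cost_low = lo$inc_cost, inc_cost_high = hi$inc_cost,
               inc_qaly_low = lo$inc_qaly, inc_qaly_high = hi$inc_qaly,
               status_low = lo$status, status_high = hi$status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), base = numeric(), low = numeric(),
               high = numeric(), icer_low = numeric(), icer_high = numeric(),
               inc_cost_low = numeric(), inc_cost_high = numeric(),
               inc_qaly_low = numeric(), inc_qaly_high = numeric(),
               status_low = character(), status_high = character(),
               stringsAsFactors = FALSE)
  attr(out, "base") <- base_run$summary
  class(out) <- c("dsa_result", "data.frame")
  out
}

#' Tornado ordering of a sensitivity analysis
#'
#' Parameters are sorted by descending ICER range `|icer_high - icer_low|`.
#' Parameters with an undefined or failed scenario are ordered after the
#' fully-ok ones by their one-sided excursion from the base ICER and
#' flagged in the `flag` column.
#'
#' @param dsa A `dsa_result`.
#' @param include,exclude Optional character vectors restricting which
#'   parameters appear.
#' @return Data frame: `parameter`, `icer_low`, `icer_high`, `status_low`,
#'   `status_high`, `width`, `flag`, ordered for plotting top-down.
#' @export
tornado_order <- function(dsa, include = NULL, exclude = NULL) {
  d <- as.data.frame(dsa)
  if (!is.null(include)) d <- d[d$parameter %in% include, ]
  if (!is.null(exclude)) d <- d[!d$parameter %in% exclude, ]
  if (nrow(d) == 0) {
    return(data.frame(parameter = character(), icer_low = numeric(),
                      icer_high = numeric(), status_low = character(),
                      status_high = character(), width = numeric(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  base_icer <- attr(dsa, "base")$icer
  ok <- d$status_low == "ok" & d$status_high == "ok"
  width <- ifelse(ok, abs(d$icer_high - d$icer_low), NA_real_)
  one_sided <- pmax(abs(d$icer_high - base_icer), abs(d$icer_low - base_icer),
                    na.rm = TRUE)
  one_sided[is.infinite(one_sided) | is.na(one_sided)] <- 0
  flag <- ifelse(ok, "",
                 ifelse(d$status_low == "engine-failure" |
                          d$status_high == "engine-failure",
                        "engine-failure", "icer-undefined"))
  ord <- order(!ok, ifelse(ok, -width, -one_sided))
  out <- data.frame(parameter = d$parameter, icer_low = d$icer_low,
                    icer_high = d$icer_high, status_low = d$status_low,
                    status_high = d$status_high, width = width, flag = flag,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  out
}
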