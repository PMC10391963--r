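# Between-arm hazard ratio estimation (Cox), proportional-hazards testing
# (scaled Schoenfeld residuals) and construction of the intervention curve
# from the control curve under a constant HR.

.two_arm_frame <- function(ipd_control, ipd_intervention) {
  if (sum(ipd_control$event) < 1 || sum(ipd_intervention$event) < 1) {
    stop_psm("degenerate-arms", "each arm needs at least one event")
  }
  data.frame(
    time = c(ipd_control$time, ipd_intervention$time),
    event = c(ipd_control$event, ipd_intervention$event),
    z = c(rep(0L, nrow(ipd_control)), rep(1L, nrow(ipd_intervention))))
}

#' Cox proportional-hazards estimate of the between-arm hazard ratio
#'
#' Maximises the partial likelihood for a single binary covariate
#' (intervention vs control) with the Efron correction for tied event times
#' (monthly-grid reconstruction produces many ties). Breslow is available
#' for cross-checking.
#'
#' @param ipd_control,ipd_intervention [psm_ipd()] sets, one per arm.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list of class `hr_estimate`: `hr`, `se_log_hr`, `ci_low`,
#'   `ci_high` (Wald 95% on the log scale), `converged`.
#' @export
cox_hr <- function(ipd_control, ipd_intervention, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- .two_arm_frame(ipd_control, ipd_intervention)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ z, data = d, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ z, data = d, ties = ties))
      attr(f, "psm_warned") <- TRUE
      f
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  warned <- isTRUE(attr(fit, "psm_warned"))
  conv <- is.finite(beta) && is.finite(se) && !warned
  if (!conv && (!is.finite(beta) || !is.finite(se) || abs(beta) > 20)) {
    # monotone likelihood / separation: flag with infinite bounds
    return(structure(list(hr = exp(beta), se_log_hr = Inf,
                          ci_low = 0, ci_high = Inf, converged = FALSE),
                     class = "hr_estimate"))
  }
  structure(list(hr = exp(beta), se_log_hr = se,
                 ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
                 converged = TRUE),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> HR %.4f (95%% CI %.4f-%.4f)%s\n", x$hr,
              x$ci_low, x$ci_high, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Test of proportional hazards
#'
#' Score test on scaled Schoenfeld residuals against a time transform
#' (Kaplan-Meier transform of event times by default, the standard choice).
#' A low p-value indicates the data are not consistent with proportional
#' hazards; the pipeline warns but does not stop, since fit judgement rests
#' with the analyst.
#'
#' @inheritParams cox_hr
#' @param transform Time transform passed to the residual test: `"km"`
#'   (default), `"rank"` or `"identity"`.
#' @return A list of class `ph_test_result`: `chisq`, `df`, `p`.
#' @export
ph_test <- function(ipd_control, ipd_intervention, transform = "km") {
  d <- .two_arm_frame(ipd_control, ipd_intervention)
  if (length(unique(d$time[d$event == 1])) < 3) {
    stop_psm("insufficient-events",
             "proportional-hazards test needs at least 3 distinct event times")
  }
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ z, data = d, ties = "efron"))
  zp <- survival::cox.zph(fit, transform = transform)
  structure(list(chisq = unname(zp$table["z", "chisq"]),
                 df = unname(zp$table["z", "df"]),
                 p = unname(zp$table["z", "p"]),
                 transform = transform),
            class = "ph_test_result")
}

#' @export
print.ph_test_result <- function(x, ...) {
  cat(sprintf("<ph_test_result> chisq %.3f on %g df, p = %.4f (%s transform)\n",
              x$chisq, x$df, x$p, x$transform))
  invisible(x)
}

#' Apply a constant hazard ratio to a survival curve
#'
#' Scales the cumulative hazard: `H_int(t) = hr * H_ctrl(t)`, equivalently
#' `S_int(t) = S_ctrl(t)^hr`. Works through the curve's cumulative-hazard
#' contract, so it is valid whatever family (proportional-hazards or
#' accelerated-failure-time metric) produced the control curve.
#'
#' @param control_curve A `psm_curve`.
#' @param hr Positive hazard ratio.
#' @return A new `psm_curve` for the intervention arm.
#' @export
apply_hr <- function(control_curve, hr) {
  if (!is.finite(hr) || hr <= 0) {
    stop_psm("invalid-parameter", "hazard ratio must be a positive number")
  }
  S0 <- control_curve$S; H0 <- control_curve$H; h0 <- control_curve$h
  new_psm_curve(
    S = function(t) S0(t)^hr,
    H = function(t) hr * H0(t),
    h = function(t) hr * h0(t),
    tag = sprintf("%s|hr=%g", control_curve$tag, hr))
}
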