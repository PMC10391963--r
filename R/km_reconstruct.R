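# Reconstruction of approximate individual patient data from digitized
# Kaplan-Meier coordinates plus the published numbers at risk, in the spirit
# of the standard published reconstruction algorithm: within each interval
# between consecutive risk-table times, the number censored is chosen so
# that, with censorings spread uniformly across the interval and event
# counts derived from successive KM probability ratios, the implied number
# at risk at the next risk-table time reproduces the published value.

#' Construct a digitized Kaplan-Meier curve
#'
#' @param endpoint `"OS"` or `"PFS"`.
#' @param arm `"intervention"` or `"control"`.
#' @param times Strictly increasing coordinate times in months, starting at 0.
#' @param surv_probs Survival probabilities at `times`; `surv_probs[1]` must
#'   be 1 and the sequence non-increasing.
#' @param risk_times Times (months) at which numbers at risk are published;
#'   must start at 0 and be a subset of `times`.
#' @param n_at_risk Non-negative, non-increasing integers along `risk_times`.
#' @param total_events Optional total event count for the curve.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(endpoint, arm, times, surv_probs,
                            risk_times, n_at_risk, total_events = NULL) {
  if (length(times) < 2 || length(times) != length(surv_probs)) {
    stop_psm("invalid-curve", "times and surv_probs must align, length >= 2")
  }
  if (any(diff(times) <= 0) || times[1] != 0) {
    stop_psm("invalid-curve", "times must be strictly increasing from 0")
  }
  if (abs(surv_probs[1] - 1) > 1e-9) {
    stop_psm("invalid-curve", "survival probability at time 0 must be 1")
  }
  if (any(diff(surv_probs) > 1e-9)) {
    stop_psm("invalid-curve",
             sprintf("survival probabilities must be non-increasing (first rise after month %g)",
                     times[which(diff(surv_probs) > 1e-9)[1]]))
  }
  if (any(surv_probs < 0) || any(surv_probs > 1)) {
    stop_psm("invalid-curve", "survival probabilities must lie in [0, 1]")
  }
  if (length(risk_times) < 1 || risk_times[1] != 0) {
    stop_psm("invalid-curve", "risk table must start at time 0")
  }
  if (length(n_at_risk) != length(risk_times)) {
    stop_psm("invalid-curve", "risk_times and n_at_risk must align")
  }
  if (any(n_at_risk < 0) || any(diff(n_at_risk) > 0)) {
    stop_psm("invalid-curve", "numbers at risk must be non-negative and non-increasing")
  }
  if (!all(risk_times %in% times)) {
    stop_psm("invalid-curve", "risk_times must be a subset of the coordinate times")
  }
  if (!is.null(total_events) && (total_events < 0 || total_events != round(total_events))) {
    stop_psm("invalid-parameter", "total_events must be a non-negative integer")
  }
  structure(list(endpoint = endpoint, arm = arm,
                 times = as.numeric(times), surv_probs = as.numeric(surv_probs),
                 risk_times = as.numeric(risk_times),
                 n_at_risk = as.integer(round(n_at_risk)),
                 total_events = if (is.null(total_events)) NULL else as.integer(total_events)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s/%s: %d monthly points to %g, n0 = %d\n",
              x$endpoint, x$arm, length(x$times), max(x$times), x$n_at_risk[1]))
  invisible(x)
}

# Walk one risk-table interval with `nc` censorings placed at uniform
# quantiles strictly inside (t_lo, t_hi). A click at coordinate time t
# carries the events that occurred in the month ending at t, so an interval
# processes the clicks in (T_j, T_{j+1}] before its end state is compared
# with the published number at risk at T_{j+1}. Event counts at each click
# come from the ratio of the published probability to the running
# reconstructed KM value, rounded to the nearest integer (ties to even).
.walk_interval <- function(n, S_run, click_t, click_S, t_lo, t_hi, nc) {
  cens_t <- if (nc > 0) t_lo + (seq_len(nc) - 0.5) / nc * (t_hi - t_lo) else numeric()
  # keep censorings off the digitized step times so risk-set order is unambiguous
  hit <- cens_t %in% click_t
  if (any(hit)) cens_t[hit] <- cens_t[hit] - (t_hi - t_lo) * 1e-6
  ev_t <- numeric(); ev_d <- integer()
  ci <- 1
  for (i in seq_along(click_t)) {
    while (ci <= nc && cens_t[ci] < click_t[i]) {  # censor before this click
      n <- n - 1
      ci <- ci + 1
    }
    d <- 0L
    if (n > 0 && S_run > 0) {
      d <- as.integer(round(n * (1 - click_S[i] / S_run)))
      d <- max(0L, min(d, n))
      if (d > 0) {
        S_run <- S_run * (1 - d / n)
        n <- n - d
      }
    }
    ev_t <- c(ev_t, click_t[i]); ev_d <- c(ev_d, d)
  }
  n_cens_used <- ci - 1
  # censors after the last click but inside the interval
  n <- n - (nc - n_cens_used)
  list(n = n, S_run = S_run, ev_t = ev_t, ev_d = ev_d,
       cens_t = cens_t, events = sum(ev_d))
}

#' Reconstruct approximate IPD from a digitized curve
#'
#' For each interval between consecutive published risk-table times the
#' number censored is found by deterministic integer search (starting from
#' the KM-implied estimate, expanding +/-1, ties broken toward fewer
#' censorings) so the implied number at risk matches the published value.
#' Censoring times are placed at uniform quantiles strictly inside each
#' interval. Beyond the last risk-table time, censoring is assumed absent
#' unless `total_events` is supplied, in which case tail censoring is
#' adjusted so the cumulative event count matches it; all subjects still at
#' risk at the last coordinate time are censored there.
#'
#' @param curve A [digitized_curve()].
#' @return A [psm_ipd()] with exactly `n_at_risk[1]` records.
#' @export
reconstruct_ipd <- function(curve) {
  if (!inherits(curve, "digitized_curve")) {
    stop_psm("invalid-curve", "reconstruct_ipd expects a digitized_curve")
  }
  tt <- curve$times; ss <- curve$surv_probs
  rt <- curve$risk_times; nr <- curve$n_at_risk
  n0 <- nr[1]
  if (n0 < 1) stop_psm("invalid-curve", "initial number at risk must be >= 1")

  n <- n0; S_run <- 1
  ev_t <- numeric(); ev_d <- integer(); cens_t <- numeric()

  # intervals between consecutive risk-table entries
  if (length(rt) >= 2) {
    for (j in seq_len(length(rt) - 1)) {
      t_lo <- rt[j]; t_hi <- rt[j + 1]
      sel <- tt > t_lo & tt <= t_hi & ss < 1 - 1e-12  # clicks in (t_lo, t_hi]
      click_t <- tt[sel]; click_S <- ss[sel]
      target <- nr[j + 1]

      base <- .walk_interval(n, S_run, click_t, click_S, t_lo, t_hi, 0L)
      guess <- max(0L, as.integer(base$n - target))
      found <- NULL
      for (off in c(0L, as.vector(rbind(-seq_len(n0), seq_len(n0))))) {
        nc <- guess + off
        if (nc < 0 || nc > n) next
        res <- .walk_interval(n, S_run, click_t, click_S, t_lo, t_hi, nc)
        if (res$n == target) { found <- res; break }
      }
      if (is.null(found)) {
        stop_psm("reconstruction-infeasible",
                 sprintf("no censoring count reproduces n at risk = %d at month %g (interval %d)",
                         target, t_hi, j))
      }
      ev_t <- c(ev_t, found$ev_t); ev_d <- c(ev_d, found$ev_d)
      cens_t <- c(cens_t, found$cens_t)
      n <- found$n; S_run <- found$S_run
    }
  }

  # tail: from the last risk-table time to the end of the digitized curve
  t_lo <- rt[length(rt)]; t_end <- tt[length(tt)]
  sel <- tt > t_lo & ss < 1 - 1e-12  # clicks after the last risk-table time
  click_t <- tt[sel]; click_S <- ss[sel]
  events_so_far <- sum(ev_d)
  tail_nc <- 0L
  if (t_end > t_lo || length(click_t)) {
    if (!is.null(curve$total_events)) {
      target_ev <- curve$total_events - events_so_far
      best <- NULL; best_diff <- Inf
      for (nc in 0:n) {
        res <- .walk_interval(n, S_run, click_t, click_S, t_lo, t_end, nc)
        dd <- abs(res$events - target_ev)
        if (dd < best_diff) { best <- res; best_diff <- dd; tail_nc <- nc }
        if (dd == 0) break
      }
      tail_res <- best
    } else {
      tail_res <- .walk_interval(n, S_run, click_t, click_S, t_lo, t_end, 0L)
    }
    ev_t <- c(ev_t, tail_res$ev_t); ev_d <- c(ev_d, tail_res$ev_d)
    cens_t <- c(cens_t, tail_res$cens_t)
    n <- tail_res$n
  }

  times <- c(rep(ev_t, ev_d), cens_t, rep(t_end, n))
  event <- c(rep(1L, sum(ev_d)), rep(0L, length(cens_t) + n))
  keep <- times > 0
  if (any(!keep)) { # defensive: a click at exactly 0 cannot carry events
    times <- times[keep]; event <- event[keep]
  }
  stopifnot(length(times) == n0)
  psm_ipd(times, event, arm = curve$arm, endpoint = curve$endpoint)
}

#' Kaplan-Meier (product-limit) estimate of an IPD set
#'
#' @param ipd A [psm_ipd()].
#' @return A list of class `km_fit` with `times` (event times), `surv`
#'   (estimate after each event time) and an evaluator `S(t)` returning the
#'   right-continuous step function with `S(0) = 1`.
#' @export
km_curve <- function(ipd) {
  if (nrow(ipd) == 0) stop_psm("invalid-curve", "empty IPD set")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd))
  tms <- sf$time; srv <- sf$surv
  S <- function(t) {
    vapply(t, function(x) {
      if (x < 0) stop_psm("invalid-parameter", "t must be >= 0")
      idx <- which(tms <= x)
      if (length(idx) == 0) 1 else srv[max(idx)]
    }, numeric(1))
  }
  structure(list(times = tms, surv = srv, n_events = sf$n.event,
                 n_risk = sf$n.risk, S = S), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d time points; final S = %.4f\n",
              length(x$times), x$surv[length(x$surv)]))
  invisible(x)
}
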