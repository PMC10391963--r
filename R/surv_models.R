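# Maximum-likelihood fitting of right-censored parametric survival models
# and the AIC "menu" used for model selection.

#' Right-censored log-likelihood
#'
#' Computes `sum(log f(t_i))` over events plus `sum(log S(t_i))` over
#' censored records for one parametric family.
#'
#' @param family Family name (see [psm_families()]).
#' @param params Named parameters in the family's natural parameterisation.
#' @param ipd A [psm_ipd()] data set.
#' @return The log-likelihood (scalar).
#' @export
censored_loglik <- function(family, params, ipd) {
  params <- .check_params(family, params)
  fam <- .get_family(family)
  ev <- ipd$event == 1
  ll <- 0
  if (any(ev)) ll <- ll + sum(fam$logdens(ipd$time[ev], params))
  if (any(!ev)) ll <- ll + sum(fam$logsurv(ipd$time[!ev], params))
  ll
}

#' Fit one parametric survival family by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimisation on an unconstrained transformation of the
#' parameters (log scale for positive parameters), started from a fixed grid
#' of five moment-based points; the best converged solution wins. Fully
#' deterministic: no randomness is used. The exponential family uses its
#' closed-form MLE `rate = events / total time`.
#'
#' Parameterisations: exponential `rate`; Weibull `shape`, `scale` with
#' `S = exp(-(t/scale)^shape)`; gamma `shape`, `rate`; log-logistic `shape`,
#' `scale` with `S = 1/(1+(t/scale)^shape)`; log-normal `meanlog`, `sdlog`;
#' Gompertz `rate`, `shape` with hazard `rate * exp(shape t)` (negative
#' `shape` allowed, giving an improper plateau — flagged with a warning);
#' generalized gamma `(mu, sigma, Q)` and generalized F `(mu, sigma, Q, P)`
#' in their stable forms.
#'
#' @param ipd A [psm_ipd()] with at least one event.
#' @param family Family name.
#' @return An object of class `psm_fit` with fields `family`, `params`,
#'   `loglik`, `aic`, `n`, `n_events`, `converged` and `notes`.
#' @export
fit_parametric <- function(ipd, family) {
  fam <- .get_family(family)
  n_ev <- sum(ipd$event)
  if (n_ev < 1) stop_psm("invalid-parameter", "need at least one event to fit")
  notes <- character()
  if (family == "generalized-F" && n_ev < 10) {
    notes <- c(notes, "generalized-F fitted on fewer than 10 events; unstable")
    warning("generalized-F fitted on fewer than 10 events; estimates may be unstable")
  }
  if (family == "exponential") {
    rate <- n_ev / sum(ipd$time)
    par <- c(rate = rate)
    ll <- censored_loglik(family, par, ipd)
    return(.new_fit(family, par, ll, nrow(ipd), n_ev, TRUE, notes))
  }

  tev <- ipd$time[ipd$event == 1]
  mlog <- mean(log(tev))
  slog <- stats::sd(log(tev))
  if (!is.finite(slog) || slog <= 0) slog <- 0.5
  starts <- fam$starts(mean(ipd$time), mlog, slog)

  negll <- function(x) {
    p <- fam$to_nat(x)
    ev <- ipd$event == 1
    v <- suppressWarnings({  # extreme trial parameters may overflow to NaN
      s <- 0
      if (any(ev)) s <- s + sum(fam$logdens(ipd$time[ev], p))
      if (any(!ev)) s <- s + sum(fam$logsurv(ipd$time[!ev], p))
      s
    })
    if (!is.finite(v)) return(1e10)
    -v
  }

  lower <- fam$lower %||% rep(-Inf, ncol(starts))
  upper <- fam$upper %||% rep(Inf, ncol(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    x0 <- pmin(pmax(starts[i, ], lower + 1e-6), upper - 1e-6)
    res <- tryCatch(
      stats::optim(x0, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    par <- fam$to_nat(starts[1, ])
    return(.new_fit(family, par, -Inf, nrow(ipd), n_ev, FALSE,
                    c(notes, "all optimisation starts failed")))
  }
  if (best$convergence != 0) {
    # line-search hiccups near the optimum are common; polish derivative-free
    pol <- tryCatch(
      stats::optim(best$par, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value + 1e-8 &&
        all(pol$par >= lower - 1e-9) && all(pol$par <= upper + 1e-9)) {
      best <- pol
    }
  }
  par <- fam$to_nat(best$par)
  conv <- best$convergence == 0
  if (family == "gompertz" && par[["shape"]] < 0) {
    notes <- c(notes, sprintf(
      "Gompertz shape < 0: improper survival with plateau %.4f",
      exp(par[["rate"]] / par[["shape"]])))
  }
  .new_fit(family, par, -best$value, nrow(ipd), n_ev, conv, notes)
}

.new_fit <- function(family, params, loglik, n, n_events, converged, notes) {
  k <- length(params)
  structure(
    list(family = family, params = as.list(params), loglik = loglik,
         aic = 2 * k - 2 * loglik, n = n, n_events = n_events,
         converged = converged, notes = notes),
    class = "psm_fit")
}

#' @export
print.psm_fit <- function(x, ...) {
  cat(sprintf("<psm_fit> %s: logLik %.4f, AIC %.4f (%d obs, %d events)%s\n",
              x$family, x$loglik, x$aic, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("  params:", paste(sprintf("%s=%.5g", names(x$params), unlist(x$params)),
                         collapse = ", "), "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Fit all eight families and rank by AIC
#'
#' @param ipd A [psm_ipd()] with at least one event.
#' @return A list of class `psm_fit_menu`: one `psm_fit` per family, sorted
#'   by AIC with non-converged fits last.
#' @export
fit_menu <- function(ipd) {
  fits <- lapply(psm_families(), function(f) {
    withCallingHandlers(
      tryCatch(fit_parametric(ipd, f), error = function(e) {
        .new_fit(f, stats::setNames(as.list(rep(NA_real_,
          length(.get_family(f)$par_names))), .get_family(f)$par_names),
          -Inf, nrow(ipd), sum(ipd$event), FALSE, conditionMessage(e))
      }),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  not_conv <- !vapply(fits, `[[`, logical(1), "converged")
  ord <- order(not_conv * 1e12 + vapply(fits, `[[`, numeric(1), "aic"))
  structure(fits[ord], class = "psm_fit_menu")
}

#' @export
print.psm_fit_menu <- function(x, ...) {
  cat("<psm_fit_menu> (sorted by AIC)\n")
  for (f in x) {
    cat(sprintf("  %-18s AIC %10.3f  logLik %10.3f  %s\n", f$family, f$aic,
                f$loglik, if (f$converged) "converged" else "FAILED"))
  }
  invisible(x)
}

#' Export a fit menu as a data frame / CSV
#'
#' @param menu A `psm_fit_menu`.
#' @param path Optional CSV path; when given the table is also written there.
#' @return Data frame with columns `family`, `params`, `loglik`, `aic`,
#'   `converged`.
#' @export
fit_menu_table <- function(menu, path = NULL) {
  d <- data.frame(
    family = vapply(menu, `[[`, character(1), "family"),
    params = vapply(menu, function(f)
      paste(sprintf("%s=%.6g", names(f$params), unlist(f$params)), collapse = "; "),
      character(1)),
    loglik = vapply(menu, `[[`, numeric(1), "loglik"),
    aic = vapply(menu, `[[`, numeric(1), "aic"),
    converged = vapply(menu, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE)
  d
}

#' Evaluate a fitted model's survival, hazard or cumulative hazard
#'
#' The three functions form a consistent triplet: `H(t) = -log S(t)` and the
#' hazard is the analytic `f(t)/S(t)` of the family.
#'
#' @param model A `psm_fit`.
#' @param t Non-negative times in months.
#' @param kind One of `"survival"`, `"hazard"`, `"cumhazard"`.
#' @return Numeric vector along `t`.
#' @export
evaluate <- function(model, t, kind = c("survival", "hazard", "cumhazard")) {
  kind <- match.arg(kind)
  if (any(t < 0)) stop_psm("invalid-parameter", "t must be >= 0")
  p <- unlist(model$params)
  switch(kind,
         survival = psm_surv(model$family, p, t),
         hazard = psm_hazard(model$family, p, t),
         cumhazard = psm_cumhaz(model$family, p, t))
}

#' Turn a fitted model into a survival-curve object
#'
#' A `psm_curve` packages `S(t)`, `H(t)` and `h(t)` closures with a
#' provenance tag; the partitioned-survival engine and [apply_hr()] work on
#' this contract and are agnostic to the underlying family.
#'
#' @param model A `psm_fit`.
#' @return A `psm_curve`.
#' @export
as_curve <- function(model) {
  p <- unlist(model$params)
  fam <- model$family
  new_psm_curve(
    S = function(t) psm_surv(fam, p, t),
    H = function(t) psm_cumhaz(fam, p, t),
    h = function(t) psm_hazard(fam, p, t),
    tag = sprintf("fitted:%s", fam))
}

#' Construct a survival curve from explicit functions
#'
#' @param S,H,h Vectorised survival, cumulative hazard and hazard functions
#'   of time in months; `S(0)` must be 1.
#' @param tag Provenance label.
#' @return A `psm_curve`.
#' @export
new_psm_curve <- function(S, H, h, tag = "custom") {
  structure(list(S = S, H = H, h = h, tag = tag), class = "psm_curve")
}

#' @export
print.psm_curve <- function(x, ...) {
  cat(sprintf("<psm_curve> %s; S(12) = %.4f\n", x$tag, x$S(12)))
  invisible(x)
}
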