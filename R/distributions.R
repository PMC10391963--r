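# Parametric survival families.
#
# Each family is registered with: parameter names, a bijection between the
# natural parameter space and an unconstrained optimisation scale, the
# log-density and log-survival functions (vectorised in t), and the inverse
# survival function used both for random sampling and for closed-form
# checks. All distributions are in "stable" parameterisations: positive
# parameters are optimised on the log scale; the generalized gamma and
# generalized F use the (mu, sigma, Q[, P]) forms whose special cases
# (Weibull, gamma, log-normal) are exact parameter substitutions.

#' Supported parametric survival families
#'
#' @return Character vector of the eight family names accepted throughout
#'   the package: `"exponential"`, `"weibull"`, `"gamma"`, `"log-logistic"`,
#'   `"log-normal"`, `"gompertz"`, `"generalized-gamma"`, `"generalized-F"`.
#' @export
psm_families <- function() {
  c("exponential", "weibull", "gamma", "log-logistic", "log-normal",
    "gompertz", "generalized-gamma", "generalized-F")
}

# ---- per-family primitives -------------------------------------------------

# Gompertz: hazard h(t) = rate * exp(shape * t), shape real (shape < 0 gives
# an improper survival plateau exp(rate/shape) -- allowed, flagged upstream).
.gomp_cumhaz <- function(t, rate, shape) {
  if (abs(shape) < 1e-12) rate * t else (rate / shape) * expm1(shape * t)
}

# Generalized gamma (stable form): location mu, scale sigma > 0, shape Q real.
# Q -> 0 is the log-normal limit; Q = 1 is Weibull(shape 1/sigma, scale
# exp(mu)); Q = sigma is gamma(shape sigma^-2, rate exp(-mu) sigma^-2).
.gengamma_logdens <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-8) return(stats::dlnorm(t, mu, sigma, log = TRUE))
  q2 <- Q^-2
  w <- (log(t) - mu) / sigma
  log(abs(Q)) - log(sigma * t) + q2 * log(q2) + q2 * (Q * w - exp(Q * w)) -
    lgamma(q2)
}

.gengamma_logsurv <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-8) return(stats::plnorm(t, mu, sigma, lower.tail = FALSE, log.p = TRUE))
  q2 <- Q^-2
  w <- (log(t) - mu) / sigma
  stats::pgamma(q2 * exp(Q * w), shape = q2, lower.tail = Q < 0, log.p = TRUE)
}

.gengamma_qsurv <- function(p, mu, sigma, Q) {
  # t such that S(t) = p
  if (abs(Q) < 1e-8) return(stats::qlnorm(p, mu, sigma, lower.tail = FALSE))
  q2 <- Q^-2
  g <- stats::qgamma(p, shape = q2, lower.tail = Q < 0)
  exp(mu + sigma * log(g / q2) / Q)
}

# Generalized F (stable form): mu, sigma > 0, Q real, P > 0; P -> 0 recovers
# the generalized gamma.
.genf_consts <- function(Q, P) {
  tmp <- Q^2 + 2 * P
  delta <- sqrt(tmp)
  list(delta = delta, s1 = 2 / (tmp + Q * delta), s2 = 2 / (tmp - Q * delta))
}

.genf_logdens <- function(t, mu, sigma, Q, P) {
  k <- .genf_consts(Q, P)
  w <- (log(t) - mu) * k$delta / sigma
  log(k$delta) + k$s1 * w + k$s1 * (log(k$s1) - log(k$s2)) - log(sigma * t) -
    (k$s1 + k$s2) * log1p(k$s1 * exp(w) / k$s2) - lbeta(k$s1, k$s2)
}

.genf_logsurv <- function(t, mu, sigma, Q, P) {
  k <- .genf_consts(Q, P)
  w <- (log(t) - mu) * k$delta / sigma
  expw <- exp(w)
  stats::pbeta(k$s1 * expw / (k$s1 * expw + k$s2), k$s1, k$s2,
               lower.tail = FALSE, log.p = TRUE)
}

.genf_qsurv <- function(p, mu, sigma, Q, P) {
  k <- .genf_consts(Q, P)
  qb <- stats::qbeta(p, k$s1, k$s2, lower.tail = FALSE)
  expw <- k$s2 * qb / (k$s1 * (1 - qb))
  exp(mu + sigma * log(expw) / k$delta)
}

# ---- registry --------------------------------------------------------------

# Each entry: par_names; to_nat / to_opt (parameter transforms); logdens(t, p);
# logsurv(t, p); qsurv(p, par) inverse survival; starts(tbar, mlog, slog)
# returning a matrix of optimisation-scale starting points (rows); optional
# lower/upper box bounds on the optimisation scale. The bounds on the
# flexible families keep the optimiser away from degenerate spike solutions
# (sigma -> 0 with |Q| large) that the likelihood admits when event times
# are heavily tied, as reconstructed monthly-grid IPD always is.
.fam_registry <- local({
  reg <- list()

  reg[["exponential"]] <- list(
    par_names = "rate",
    to_nat = function(x) c(rate = exp(x[1])),
    to_opt = function(p) log(p[["rate"]]),
    logdens = function(t, p) stats::dexp(t, p[["rate"]], log = TRUE),
    logsurv = function(t, p) -p[["rate"]] * t,
    qsurv = function(u, p) -log(u) / p[["rate"]],
    starts = function(tbar, mlog, slog) matrix(log(1 / tbar) + c(-1, -0.5, 0, 0.5, 1), ncol = 1)
  )

  reg[["weibull"]] <- list(
    par_names = c("shape", "scale"),
    to_nat = function(x) c(shape = exp(x[1]), scale = exp(x[2])),
    to_opt = function(p) log(c(p[["shape"]], p[["scale"]])),
    logdens = function(t, p) stats::dweibull(t, p[["shape"]], p[["scale"]], log = TRUE),
    logsurv = function(t, p) -(t / p[["scale"]])^p[["shape"]],
    qsurv = function(u, p) p[["scale"]] * (-log(u))^(1 / p[["shape"]]),
    starts = function(tbar, mlog, slog) {
      k0 <- 1.2 / max(slog, 0.1)
      cbind(log(c(k0, k0 / 2, k0 * 2, 1, k0)), c(mlog, mlog, mlog, log(tbar), mlog + 1))
    }
  )

  reg[["gamma"]] <- list(
    par_names = c("shape", "rate"),
    to_nat = function(x) c(shape = exp(x[1]), rate = exp(x[2])),
    to_opt = function(p) log(c(p[["shape"]], p[["rate"]])),
    logdens = function(t, p) stats::dgamma(t, p[["shape"]], p[["rate"]], log = TRUE),
    logsurv = function(t, p) stats::pgamma(t, p[["shape"]], p[["rate"]],
                                           lower.tail = FALSE, log.p = TRUE),
    qsurv = function(u, p) stats::qgamma(u, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    starts = function(tbar, mlog, slog) {
      a0 <- 1 / max(slog^2, 0.05)
      cbind(log(c(a0, a0 / 3, a0 * 3, 1, a0)), log(c(a0, a0 / 3, a0 * 3, 1, a0) / tbar))
    }
  )

  reg[["log-logistic"]] <- list(
    par_names = c("shape", "scale"),
    to_nat = function(x) c(shape = exp(x[1]), scale = exp(x[2])),
    to_opt = function(p) log(c(p[["shape"]], p[["scale"]])),
    logdens = function(t, p) {
      k <- p[["shape"]]; s <- p[["scale"]]
      z <- (t / s)^k
      log(k / s) + (k - 1) * (log(t) - log(s)) - 2 * log1p(z)
    },
    logsurv = function(t, p) -log1p((t / p[["scale"]])^p[["shape"]]),
    qsurv = function(u, p) p[["scale"]] * (1 / u - 1)^(1 / p[["shape"]]),
    starts = function(tbar, mlog, slog) {
      k0 <- 1.8 / max(slog, 0.1)
      cbind(log(c(k0, k0 / 2, k0 * 2, 1, k0)), c(mlog, mlog, mlog, log(tbar), mlog + 1))
    }
  )

  reg[["log-normal"]] <- list(
    par_names = c("meanlog", "sdlog"),
    to_nat = function(x) c(meanlog = x[1], sdlog = exp(x[2])),
    to_opt = function(p) c(p[["meanlog"]], log(p[["sdlog"]])),
    logdens = function(t, p) stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE),
    logsurv = function(t, p) stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                                           lower.tail = FALSE, log.p = TRUE),
    qsurv = function(u, p) stats::qlnorm(u, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    starts = function(tbar, mlog, slog) {
      cbind(c(mlog, mlog - 0.5, mlog + 0.5, mlog, mlog),
            log(c(slog, slog, slog, slog / 2, slog * 2)))
    }
  )

  reg[["gompertz"]] <- list(
    par_names = c("rate", "shape"),
    to_nat = function(x) c(rate = exp(x[1]), shape = x[2]),
    to_opt = function(p) c(log(p[["rate"]]), p[["shape"]]),
    logdens = function(t, p) {
      log(p[["rate"]]) + p[["shape"]] * t - .gomp_cumhaz(t, p[["rate"]], p[["shape"]])
    },
    logsurv = function(t, p) -.gomp_cumhaz(t, p[["rate"]], p[["shape"]]),
    qsurv = function(u, p) {
      a <- p[["rate"]]; b <- p[["shape"]]
      if (abs(b) < 1e-12) return(-log(u) / a)
      arg <- 1 - b * log(u) / a
      ifelse(arg > 0, log(arg) / b, Inf)  # b < 0 plateau: S never reaches u
    },
    starts = function(tbar, mlog, slog) {
      cbind(log(1 / tbar) + c(0, -1, 1, 0, 0), c(0, 0, 0, 0.05, -0.05))
    }
  )

  reg[["generalized-gamma"]] <- list(
    par_names = c("mu", "sigma", "Q"),
    to_nat = function(x) c(mu = x[1], sigma = exp(x[2]), Q = x[3]),
    to_opt = function(p) c(p[["mu"]], log(p[["sigma"]]), p[["Q"]]),
    logdens = function(t, p) .gengamma_logdens(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    logsurv = function(t, p) .gengamma_logsurv(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    qsurv = function(u, p) .gengamma_qsurv(u, p[["mu"]], p[["sigma"]], p[["Q"]]),
    starts = function(tbar, mlog, slog) {
      cbind(c(mlog, mlog, mlog, mlog - 0.5, mlog + 0.5),
            log(c(slog, slog / 2, slog * 2, slog, slog)),
            c(0, 1, -0.5, 0.5, 1))
    },
    lower = c(-50, log(0.05), -6), upper = c(50, log(100), 6)
  )

  reg[["generalized-F"]] <- list(
    par_names = c("mu", "sigma", "Q", "P"),
    to_nat = function(x) c(mu = x[1], sigma = exp(x[2]), Q = x[3], P = exp(x[4])),
    to_opt = function(p) c(p[["mu"]], log(p[["sigma"]]), p[["Q"]], log(p[["P"]])),
    logdens = function(t, p) .genf_logdens(t, p[["mu"]], p[["sigma"]], p[["Q"]], p[["P"]]),
    logsurv = function(t, p) .genf_logsurv(t, p[["mu"]], p[["sigma"]], p[["Q"]], p[["P"]]),
    qsurv = function(u, p) .genf_qsurv(u, p[["mu"]], p[["sigma"]], p[["Q"]], p[["P"]]),
    starts = function(tbar, mlog, slog) {
      cbind(c(mlog, mlog, mlog, mlog - 0.5, mlog + 0.5),
            log(c(slog, slog / 2, slog * 2, slog, slog)),
            c(0, 1, -0.5, 0.5, 1),
            log(c(0.5, 0.5, 1, 0.2, 1)))
    },
    lower = c(-50, log(0.05), -6, log(1e-4)),
    upper = c(50, log(100), 6, log(100))
  )

  reg
})

.get_family <- function(family) {
  fam <- .fam_registry[[family]]
  if (is.null(fam)) {
    stop_psm("invalid-parameter",
             sprintf("unknown survival family '%s'; choose one of: %s",
                     family, paste(psm_families(), collapse = ", ")))
  }
  fam
}

.check_params <- function(family, params) {
  fam <- .get_family(family)
  if (!all(fam$par_names %in% names(params))) {
    stop_psm("invalid-parameter",
             sprintf("family '%s' needs parameters: %s", family,
                     paste(fam$par_names, collapse = ", ")))
  }
  params <- params[fam$par_names]
  pos <- switch(family,
    "exponential" = "rate",
    "weibull" = c("shape", "scale"),
    "gamma" = c("shape", "rate"),
    "log-logistic" = c("shape", "scale"),
    "log-normal" = "sdlog",
    "gompertz" = "rate",
    "generalized-gamma" = "sigma",
    "generalized-F" = c("sigma", "P"))
  bad <- pos[!vapply(pos, function(nm) is.finite(params[[nm]]) && params[[nm]] > 0, logical(1))]
  if (length(bad) || any(!is.finite(unlist(params)))) {
    stop_psm("invalid-parameter",
             sprintf("parameters out of domain for family '%s' (%s must be positive and all finite)",
                     family, paste(pos, collapse = ", ")))
  }
  params
}

#' Evaluate survival-distribution primitives for one family
#'
#' Low-level access to the density, survival, hazard, cumulative hazard and
#' inverse-survival functions of the eight supported families. Higher-level
#' code goes through [evaluate()] on a fitted model; these are exposed for
#' validation and simulation.
#'
#' @param family Family name, one of [psm_families()].
#' @param params Named list/vector of parameters in the family's natural
#'   parameterisation (see Details of [fit_parametric()]).
#' @param t Non-negative times (months).
#' @param u Survival probabilities in (0, 1] for `psm_qsurv`.
#' @return `psm_dens`, `psm_surv`, `psm_cumhaz`, `psm_hazard`: numeric vector
#'   along `t`. `psm_qsurv`: times at which survival equals `u`.
#' @export
psm_surv <- function(family, params, t) {
  params <- .check_params(family, params)
  fam <- .get_family(family)
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- 1
  if (any(pos)) out[pos] <- exp(fam$logsurv(t[pos], params))
  out
}

#' @rdname psm_surv
#' @export
psm_dens <- function(family, params, t) {
  params <- .check_params(family, params)
  fam <- .get_family(family)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) out[pos] <- exp(fam$logdens(t[pos], params))
  out
}

#' @rdname psm_surv
#' @export
psm_cumhaz <- function(family, params, t) {
  params <- .check_params(family, params)
  fam <- .get_family(family)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) out[pos] <- -fam$logsurv(t[pos], params)
  out
}

#' @rdname psm_surv
#' @export
psm_hazard <- function(family, params, t) {
  params <- .check_params(family, params)
  fam <- .get_family(family)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) out[pos] <- exp(fam$logdens(t[pos], params) - fam$logsurv(t[pos], params))
  out
}

#' @rdname psm_surv
#' @export
psm_qsurv <- function(family, params, u) {
  params <- .check_params(family, params)
  if (any(u <= 0 | u > 1)) stop_psm("invalid-parameter", "u must be in (0, 1]")
  fam <- .get_family(family)
  out <- fam$qsurv(u, params)
  out[u == 1] <- 0
  out
}

# Random event times: inverse-survival sampling (uses the session RNG).
.rsurv <- function(n, family, params) {
  psm_qsurv(family, params, stats::runif(n))
}
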