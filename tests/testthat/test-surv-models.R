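# MLE fitting, AIC menu and curve evaluation.

test_that("exponential closed forms: loglik, MLE and AIC", {
  ipd <- psm_ipd(c(1, 2, 3, 4), c(1, 1, 1, 1))
  # 4 log(lambda) - lambda * 10 at lambda = 0.4
  expect_equal(censored_loglik("exponential", c(rate = 0.4), ipd),
               4 * log(0.4) - 4, tolerance = 1e-12)
  expect_equal(censored_loglik("exponential", c(rate = 0.4), ipd),
               -7.6652, tolerance = 1e-4)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$params$rate, 0.4)  # d / sum(t) exactly
  expect_equal(fit$aic, 2 - 2 * (4 * log(0.4) - 4), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("censoring enters the likelihood through log S", {
  ipd <- psm_ipd(c(2, 5), c(1, 0))
  lam <- 0.3
  expect_equal(censored_loglik("exponential", c(rate = lam), ipd),
               dexp(2, lam, log = TRUE) - lam * 5, tolerance = 1e-12)
})

test_that("Weibull with shape 1 equals exponential with rate 1/scale", {
  set.seed(3)
  ipd <- psm_ipd(rexp(30, 0.1) + 0.05, rep(c(1, 0), 15))
  expect_equal(censored_loglik("weibull", c(shape = 1, scale = 8), ipd),
               censored_loglik("exponential", c(rate = 1 / 8), ipd),
               tolerance = 1e-10)
})

test_that("Weibull parameter recovery on simulated data", {
  set.seed(2024)
  n <- 2000
  tt <- rweibull(n, 1.3, 20)
  cens <- quantile(tt, 0.7)  # ~30% administrative censoring
  ipd <- psm_ipd(pmin(tt, cens), as.integer(tt <= cens))
  fit <- fit_parametric(ipd, "weibull")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$shape - 1.3), 0.1)
})

test_that("fit is deterministic", {
  set.seed(5)
  ipd <- psm_ipd(rweibull(150, 1.2, 12), rbinom(150, 1, 0.8))
  ipd$event[1] <- 1L
  f1 <- fit_parametric(ipd, "generalized-gamma")
  f2 <- fit_parametric(ipd, "generalized-gamma")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fit_menu covers all families, honours the AIC definition and sorts", {
  set.seed(8)
  tt <- rexp(400, 0.06)
  cens <- 30
  ipd <- psm_ipd(pmin(tt, cens), as.integer(tt <= cens))
  menu <- fit_menu(ipd)
  expect_length(menu, 8)
  expect_setequal(vapply(menu, `[[`, character(1), "family"), psm_families())
  for (f in menu) {
    if (f$converged) {
      expect_equal(f$aic, 2 * length(f$params) - 2 * f$loglik, tolerance = 1e-9)
    }
  }
  aics <- vapply(menu, `[[`, numeric(1), "aic")
  conv <- vapply(menu, `[[`, logical(1), "converged")
  expect_true(all(diff(aics[conv]) >= -1e-9))  # converged block sorted
  if (any(!conv)) expect_true(all(which(!conv) > max(which(conv))))
  # exponential data: exponential competitive with the best fit
  exp_aic <- aics[vapply(menu, `[[`, character(1), "family") == "exponential"]
  expect_lt(exp_aic - min(aics[conv]), 2)
})

test_that("generalized-F on very few events is flagged", {
  ipd <- psm_ipd(c(3, 6, 9, 12), c(1, 0, 0, 0))
  expect_warning(fit <- fit_parametric(ipd, "generalized-F"),
                 "fewer than 10 events")
  expect_true(any(grepl("fewer than 10 events", fit$notes)))
  menu <- fit_menu(ipd)  # menu muffles the warning but keeps the note
  gf <- menu[[which(vapply(menu, `[[`, character(1), "family") == "generalized-F")]]
  expect_true(any(grepl("fewer than 10 events", gf$notes)))
})

test_that("evaluate returns a consistent triplet and guards t < 0", {
  fit <- exact_exp_fit(0.05)
  tt <- c(0, 1, 12, 60)
  expect_equal(evaluate(fit, 0), 1)
  expect_equal(evaluate(fit, tt), exp(-0.05 * tt))
  expect_equal(evaluate(fit, tt, "cumhazard"), 0.05 * tt)
  expect_equal(evaluate(fit, tt[-1], "hazard"), rep(0.05, 3))
  expect_error(evaluate(fit, -1), class = "psmforge_invalid_parameter")
})

test_that("MLE is invariant to time rescaling", {
  set.seed(17)
  tt <- rweibull(500, 1.4, 14)
  ev <- as.integer(tt <= 25); tt <- pmin(tt, 25)
  c_scale <- 12
  for (fam in c("weibull", "log-normal")) {
    f1 <- fit_parametric(psm_ipd(tt, ev), fam)
    f2 <- fit_parametric(psm_ipd(tt * c_scale, ev), fam)
    if (fam == "weibull") {
      expect_equal(f2$params$shape, f1$params$shape, tolerance = 1e-3)
      expect_equal(f2$params$scale, f1$params$scale * c_scale, tolerance = 1e-3)
    } else {
      expect_equal(f2$params$sdlog, f1$params$sdlog, tolerance = 1e-3)
      expect_equal(f2$params$meanlog, f1$params$meanlog + log(c_scale),
                   tolerance = 1e-3)
    }
    # Jacobian of the time rescaling shifts the density terms by -d log c
    expect_equal(f2$loglik, f1$loglik - sum(ev) * log(c_scale), tolerance = 1e-4)
  }
})
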