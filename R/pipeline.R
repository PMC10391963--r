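# End-to-end orchestration: digitized curves -> IPD -> parametric fits ->
# hazard ratios -> partitioned survival model -> sensitivity analysis.

#' Run the full modelling pipeline
#'
#' Reconstructs IPD from the four digitized curves, fits the chosen
#' parametric family to the control arm for each endpoint, resolves the
#' hazard ratios (template values take precedence; Cox estimation only when
#' the template says `"estimate"` — no silent mixing), tests proportional
#' hazards (a warning, never a stop, when p < 0.05), runs the partitioned
#' survival engine and, when requested, the univariate sensitivity analysis.
#'
#' @param inputs A `psm_inputs` object.
#' @param dsa Logical: also run the sensitivity analysis?
#' @param correction Half-cycle correction variant, see [state_occupancy()].
#' @return List of class `psm_pipeline`: `ipd` (list of four `psm_ipd`),
#'   `fits` (`pfs`, `os` control-arm fits), `hr` (resolved values and, when
#'   estimated, the `hr_estimate` objects), `ph_tests`, `results`
#'   (`psm_results`), `dsa` (`dsa_result` or `NULL`), `inputs` (with
#'   hazard ratios resolved to numbers).
#' @export
run_pipeline <- function(inputs, dsa = TRUE,
                         correction = c("trapezoid", "midpoint")) {
  correction <- match.arg(correction)
  ipd <- lapply(inputs$curves, reconstruct_ipd)
  fits <- list(pfs = fit_parametric(ipd$pfs_control, inputs$dist_pfs),
               os = fit_parametric(ipd$os_control, inputs$dist_os))

  hr_detail <- list()
  for (ep in c("os", "pfs")) {
    field <- paste0("hr_", ep)
    if (identical(inputs[[field]], "estimate")) {
      est <- cox_hr(ipd[[paste0(ep, "_control")]],
                    ipd[[paste0(ep, "_intervention")]])
      inputs[[field]] <- est$hr
      hr_detail[[field]] <- est
    }
  }

  ph_tests <- list()
  for (ep in c("os", "pfs")) {
    ph_tests[[ep]] <- tryCatch(
      ph_test(ipd[[paste0(ep, "_control")]], ipd[[paste0(ep, "_intervention")]]),
      psmforge_error = function(e) e)
    p <- ph_tests[[ep]]$p
    if (!is.null(p) && is.finite(p) && p < 0.05) {
      warning(sprintf(paste0(
        "proportional-hazards test for %s has p = %.4f (< 0.05): the data are ",
        "not consistent with a constant hazard ratio; interpret with care"),
        toupper(ep), p), call. = FALSE)
    }
  }

  results <- run_psm(inputs, fits$pfs, fits$os, correction)
  dsa_res <- if (dsa && length(inputs$dsa_ranges)) {
    run_dsa(inputs, fits$pfs, fits$os, correction)
  } else NULL

  structure(list(ipd = ipd, fits = fits,
                 hr = list(hr_os = inputs$hr_os, hr_pfs = inputs$hr_pfs,
                           detail = hr_detail),
                 ph_tests = ph_tests, results = results, dsa = dsa_res,
                 inputs = inputs),
            class = "psm_pipeline")
}

#' @export
print.psm_pipeline <- function(x, ...) {
  cat(sprintf("<psm_pipeline> HR: OS %.4f, PFS %.4f; fits: PFS %s (AIC %.1f), OS %s (AIC %.1f)\n",
              x$hr$hr_os, x$hr$hr_pfs,
              x$fits$pfs$family, x$fits$pfs$aic,
              x$fits$os$family, x$fits$os$aic))
  for (ep in names(x$ph_tests)) {
    t <- x$ph_tests[[ep]]
    if (inherits(t, "ph_test_result")) {
      cat(sprintf("  PH test %s: p = %.4f\n", toupper(ep), t$p))
    }
  }
  print(x$results)
  invisible(x)
}

#' AIC menus for both endpoints of the control arm
#'
#' @param inputs A `psm_inputs`.
#' @return List with `pfs` and `os`, each a `psm_fit_menu`.
#' @export
pipeline_fit_menus <- function(inputs) {
  list(pfs = fit_menu(reconstruct_ipd(inputs$curves$pfs_control)),
       os = fit_menu(reconstruct_ipd(inputs$curves$os_control)))
}
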