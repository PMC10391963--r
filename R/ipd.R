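#' Construct an individual-patient-data set
#'
#' A `psm_ipd` is a data frame of right-censored time-to-event records with
#' columns `time` (months, > 0), `event` (1 = event, 0 = censored), `arm`
#' (`"intervention"` or `"control"`) and `endpoint` (`"OS"` or `"PFS"`).
#'
#' @param time Positive event/censoring times in months.
#' @param event 0/1 event indicators.
#' @param arm,endpoint Labels recycled across records.
#' @return A data frame of class `psm_ipd`.
#' @export
psm_ipd <- function(time, event, arm = "control", endpoint = "OS") {
  if (length(time) == 0) stop_psm("invalid-curve", "IPD set must be non-empty")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_psm("invalid-parameter", "IPD times must be finite and > 0")
  }
  if (!all(event %in% c(0, 1))) {
    stop_psm("invalid-parameter", "event indicator must be 0 or 1")
  }
  out <- data.frame(time = as.numeric(time), event = as.integer(event),
                    arm = arm, endpoint = endpoint,
                    stringsAsFactors = FALSE)
  class(out) <- c("psm_ipd", "data.frame")
  out
}

#' @export
print.psm_ipd <- function(x, ...) {
  cat(sprintf("<psm_ipd> %d records (%d events, %d censored) [%s/%s]\n",
              nrow(x), sum(x$event), sum(1 - x$event),
              paste(unique(x$endpoint), collapse = ","),
              paste(unique(x$arm), collapse = ",")))
  invisible(x)
}

#' Read or write IPD as a 4-column CSV
#'
#' Audit/interchange format only: the modelling pipeline always starts from
#' digitized curves, not external IPD.
#'
#' @param ipd A `psm_ipd`.
#' @param path CSV file path.
#' @return `write_ipd_csv` returns `path` invisibly; `read_ipd_csv` returns a
#'   `psm_ipd`.
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  psm_ipd(d$time, d$event, d$arm, d$endpoint)
}
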