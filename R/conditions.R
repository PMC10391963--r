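# Structured error conditions. Every user-facing failure carries a short
# machine-readable `code` (e.g. "invalid-curve") so callers and the DSA sweep
# can branch on it without parsing messages.

psm_error <- function(code, message, ..., call = NULL) {
  structure(
    class = c(paste0("psmforge_", gsub("-", "_", code)), "psmforge_error",
              "error", "condition"),
    list(message = message, call = call, code = code, ...)
  )
}

stop_psm <- function(code, message, ...) {
  stop(psm_error(code, message, ...))
}

#' Extract the psmforge error code from a condition
#'
#' @param cond A condition object.
#' @return The short error code string (e.g. `"invalid-curve"`), or `NA` if
#'   the condition was not raised by psmforge.
#' @export
psm_error_code <- function(cond) {
  if (inherits(cond, "psmforge_error")) cond$code else NA_character_
}
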