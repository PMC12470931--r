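# shared constants and small helpers

#' Unit conversion: 1 mmHg in dyn/cm^2
#' @keywords internal
MMHG <- 1333.22

#' Round half-up (display rounding)
#'
#' Rounds half-way cases away from zero, the convention used for printed
#' percentages and coefficients in clinical tables (base `round()` rounds
#' half to even).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ffrct <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ffrct_error")))
}
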