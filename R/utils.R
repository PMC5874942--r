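# Internal helpers: structured error conditions and console-style rounding.

abort_fct <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fetalct_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Round half up, console style
#'
#' CT consoles and printed dose tables round .5 upwards (round-half-up), unlike
#' R's [round()], which rounds half to even. Used for displayed CTDIvol, DLP and
#' conversion-factor values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.055, 2) # 0.06, where round(0.055, 2) gives 0.05 or 0.06
#' round_half_up(100.92)   # 101
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny nudge guards against binary representation of exact halves (e.g. 0.055)
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
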