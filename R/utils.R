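#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.5 -> 1, -0.5 -> -1),
#' the convention of the published subsite tables this package reproduces.
#' Base \code{round()} rounds half to even and cannot be used for report
#' formatting here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @export
#' @examples
#' roundHalfAway(c(0.05, -0.05, 2.675), 1)
roundHalfAway <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a percentage for reports
#'
#' Percentages are reported at one decimal, rounded half away from zero
#' through a two-decimal intermediate. The two-stage rounding matches the
#' convention observable in published CEP specificity tables (e.g. 6/11 =
#' 54.5454... is printed 54.6: 54.5454 -> 54.55 -> 54.6).
#'
#' @param x numeric vector of percentages.
#' @return numeric vector rounded to one decimal.
#' @export
formatPercent <- function(x) {
  roundHalfAway(roundHalfAway(x, 2), 1)
}

#' Format a Kn coefficient for reports
#'
#' Two decimals, half away from zero, applied to the unrounded coefficient.
#'
#' @param x numeric vector of Kn values.
#' @return numeric vector rounded to two decimals.
#' @export
formatKn <- function(x) {
  roundHalfAway(x, 2)
}

# Internal: stop() with a consistent error class so callers/tests can
# distinguish validation failures from programming errors.
cepStop <- function(fmt, ..., class = "cep_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
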