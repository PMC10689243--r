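#' Trapezoidal integral
#'
#' @param x ordinate values (strictly increasing).
#' @param y values of the integrand at `x`.
#' @return The trapezoidal approximation to the integral of y over x.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Construct a delta-F/F0 trace
#'
#' A `dff_trace` holds a thresholded calcium trace in percent delta-F/F0
#' together with its sampling rate and the thresholding applied.
#'
#' @param values numeric vector, percent delta-F/F0 per frame (nonnegative
#'   after thresholding).
#' @param rate_hz sampling rate in frames per second.
#' @param threshold_pct sub-threshold zeroing level in percent delta-F/F0.
#' @param f0_definition optional list recording how the baseline F0 was
#'   estimated.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(values, rate_hz, threshold_pct = 15, f0_definition = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2L, is.finite(rate_hz), rate_hz > 0)
  structure(
    list(values = as.numeric(values), rate_hz = rate_hz,
         threshold_pct = threshold_pct, f0_definition = f0_definition),
    class = "dff_trace"
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  dur <- length(x$values) / x$rate_hz
  cat(sprintf("dff_trace: %d frames @ %.3g Hz (%.1f s), threshold %.3g%% dFF\n",
              length(x$values), x$rate_hz, dur, x$threshold_pct))
  cat(sprintf("  active frames: %d (%.1f%%), max %.1f%%\n",
              sum(x$values > 0), 100 * mean(x$values > 0), max(x$values)))
  invisible(x)
}

# Coerce numeric vectors to dff_trace when a rate is known from context.
as_dff <- function(x, rate_hz) {
  if (inherits(x, "dff_trace")) x else dff_trace(x, rate_hz)
}

#' Percentage from a count pair
#'
#' Population summaries report proportions such as the fraction of spines
#' weakened after overstimulation as a percentage of a numerator over a
#' denominator (e.g. weakened spines over all imaged spines).
#'
#' @param numerator nonnegative count(s).
#' @param denominator positive count(s).
#' @param digits digits to round the percentage to; `NULL` for unrounded.
#'   Printed summaries conventionally use one decimal place for spine
#'   population fractions and two for rare-event fractions.
#' @return Percentage value(s), `100 * numerator / denominator`.
#' @examples
#' population_fraction(435, 531)  # 81.9
#' @export
population_fraction <- function(numerator, denominator, digits = 1) {
  stopifnot(all(numerator >= 0), all(denominator > 0), all(numerator <= denominator))
  pct <- 100 * numerator / denominator
  if (!is.null(digits)) pct <- round(pct, digits) else pct
  pct
}
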