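# Interval arithmetic for rounding-aware p-value comparison. Printed
# numbers stand for a whole interval of unrounded source values; two
# reported quantities are "consistent" when the intervals they imply share
# at least one point.

#' Probability interval with explicit bound inclusivity
#'
#' @param lower,upper interval endpoints, `0 <= lower <= upper <= 1`.
#' @param lower_closed,upper_closed is the respective endpoint included?
#' @return An object of class `p_interval` (a named list).
#' @export
p_interval <- function(lower, upper, lower_closed = TRUE,
                       upper_closed = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (is.na(lower) || is.na(upper) || lower < 0 || upper > 1 || lower > upper)
    stop("invalid probability interval [", lower, ", ", upper, "]",
         call. = FALSE)
  if (lower == upper && !(lower_closed && upper_closed))
    stop("empty interval: degenerate endpoints must both be closed",
         call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 lower_closed = isTRUE(lower_closed),
                 upper_closed = isTRUE(upper_closed)),
            class = "p_interval")
}

#' @export
print.p_interval <- function(x, ...) {
  cat(sprintf("%s%.6g, %.6g%s\n",
              if (x$lower_closed) "[" else "(", x$lower, x$upper,
              if (x$upper_closed) "]" else ")"))
  invisible(x)
}

.interval_contains <- function(iv, x) {
  (x > iv$lower || (x == iv$lower && iv$lower_closed)) &&
    (x < iv$upper || (x == iv$upper && iv$upper_closed))
}

#' Do two probability intervals share at least one point?
#'
#' Respects endpoint inclusivity: intervals touching in a single point
#' overlap only if that point belongs to both.
#'
#' @param a,b [p_interval] objects.
#' @return logical scalar.
#' @export
interval_overlap <- function(a, b) {
  stopifnot(inherits(a, "p_interval"), inherits(b, "p_interval"))
  lo <- max(a$lower, b$lower)
  hi <- min(a$upper, b$upper)
  if (lo > hi) return(FALSE)
  if (lo < hi) return(TRUE)
  .interval_contains(a, lo) && .interval_contains(b, lo)
}

#' Interval of source values that round to a printed number
#'
#' Under half-up rounding, a value printed as `value` with `decimals`
#' digits stands for any source value in
#' `[value - 0.5 * 10^-decimals, value + 0.5 * 10^-decimals)`: a statistic
#' printed as 2.5 could be any value from 2.45 up to (but not including)
#' 2.55, of which 2.54 is the largest two-decimal member.
#'
#' @param value the printed number.
#' @param decimals number of digits after the decimal separator (>= 0).
#' @return list with `low`, `high`, `low_closed` (`TRUE`), `high_closed`
#'   (`FALSE`). Not clamped: callers clamp to the statistic's domain.
#' @export
rounding_interval <- function(value, decimals) {
  stopifnot(is.numeric(value), length(value) == 1L,
            decimals >= 0, decimals == as.integer(decimals))
  half <- 0.5 * 10^(-decimals)
  list(low = value - half, high = value + half,
       low_closed = TRUE, high_closed = FALSE)
}
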