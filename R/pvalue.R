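#' Recompute the p-value implied by a test statistic
#'
#' Given a test family, degrees of freedom and statistic value, returns the
#' p-value the statistic implies. t, Z and correlation tests are two-tailed
#' by default (tails = "one" halves the p exactly); F, chi-squared and the
#' meta-analytic Q tests (which follow a chi-squared distribution) are
#' always upper-tail, so `tails` is ignored for them. A correlation is
#' converted to a t statistic via \eqn{t = r \sqrt{df / (1 - r^2)}} with the
#' reported degrees of freedom (conventionally n - 2).
#'
#' @param test_type one of `"T"`, `"F"`, `"CHI2"`, `"Z"`, `"R"`, `"Q"`,
#'   `"QW"`, `"QB"`.
#' @param df1 degrees of freedom (numerator df for F); ignored for Z.
#' @param df2 denominator degrees of freedom, F only.
#' @param stat_value the test-statistic value (a correlation in `[-1, 1]`
#'   for `"R"`).
#' @param tails `"two"` (default) or `"one"`; applies to T, Z, R only.
#' @return probability in `[0, 1]`.
#' @examples
#' compute_p("T", df1 = 28, stat_value = 2.14)          # ~0.0412
#' compute_p("CHI2", df1 = 1, stat_value = 3.78)        # ~0.0519
#' @export
compute_p <- function(test_type, df1 = NA_real_, df2 = NA_real_,
                      stat_value, tails = c("two", "one")) {
  tails <- match.arg(tails)
  test_type <- match.arg(test_type,
                         c("T", "F", "CHI2", "Z", "R", "Q", "QW", "QB"))
  if (test_type != "Z" && (is.na(df1) || df1 <= 0))
    stop("df1 must be > 0 for test type ", test_type, call. = FALSE)
  if (test_type == "F" && (is.na(df2) || df2 <= 0))
    stop("df2 must be > 0 for F tests", call. = FALSE)

  p <- switch(
    test_type,
    T = {
      tail <- stats::pt(abs(stat_value), df = df1, lower.tail = FALSE)
      if (tails == "two") 2 * tail else tail
    },
    Z = {
      tail <- stats::pnorm(abs(stat_value), lower.tail = FALSE)
      if (tails == "two") 2 * tail else tail
    },
    R = {
      r <- stat_value
      if (abs(r) > 1)
        stop("|r| must be <= 1 for correlation tests", call. = FALSE)
      if (abs(r) == 1) return(0)
      tstat <- r * sqrt(df1 / (1 - r^2))
      tail <- stats::pt(abs(tstat), df = df1, lower.tail = FALSE)
      if (tails == "two") 2 * tail else tail
    },
    F = stats::pf(stat_value, df1 = df1, df2 = df2, lower.tail = FALSE),
    # Q statistics follow a chi-squared distribution
    CHI2 = , Q = , QW = , QB =
      stats::pchisq(stat_value, df = df1, lower.tail = FALSE)
  )
  min(max(p, 0), 1)
}

# vectorized convenience used internally
.compute_p_record <- function(rec, stat_value = rec$stat_value,
                              tails = "two") {
  compute_p(rec$test_type, df1 = rec$df1, df2 = rec$df2,
            stat_value = stat_value, tails = tails)
}
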