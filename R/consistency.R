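#' Checking configuration
#'
#' @param alpha significance level used to separate inconsistencies from
#'   gross inconsistencies. Default 0.05.
#' @param one_tailed_txt apply the one-tailed correction when the document
#'   contains one-tailed language? Default `TRUE`.
#' @param p_equal_alpha_sig is a reported `p = alpha` counted as
#'   significant? Default `TRUE`.
#' @param recursive recurse into subdirectories when checking a directory?
#' @param output_path optional CSV output path used by [run_check()]
#'   wrappers.
#' @return list of class `consist_config`.
#' @export
consist_config <- function(alpha = 0.05, one_tailed_txt = TRUE,
                           p_equal_alpha_sig = TRUE, recursive = FALSE,
                           output_path = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(list(alpha = alpha,
                 one_tailed_txt = isTRUE(one_tailed_txt),
                 p_equal_alpha_sig = isTRUE(p_equal_alpha_sig),
                 recursive = isTRUE(recursive),
                 output_path = output_path),
            class = "consist_config")
}

#' Interval of p-values implied by a printed test statistic
#'
#' Maps the statistic's rounding interval through [compute_p()]. Because
#' the tail probability is decreasing in the statistic's magnitude, the
#' p interval endpoints are the recomputed p at the upper and lower bounds
#' of the statistic interval; the lower p endpoint is open because the
#' statistic's upper rounding bound is excluded. Sign-symmetric statistics
#' (t, Z, r) use the magnitude of the printed value; bounds falling outside
#' the statistic's domain are clamped (giving a closed p endpoint).
#'
#' @param record one extracted statistic (a one-row data.frame or list with
#'   the fields produced by [find_statistics()]); `stat_comparator` must be
#'   `"EQ"`.
#' @param tails `"two"` or `"one"`, passed to [compute_p()].
#' @return a [p_interval].
#' @export
computed_p_interval <- function(record, tails = "two") {
  if (record$stat_comparator != "EQ")
    stop("computed_p_interval requires an exactly-reported statistic",
         call. = FALSE)
  ri <- rounding_interval(abs(record$stat_value), record$stat_decimals)
  s_lo <- ri$low
  lo_closed <- TRUE
  if (s_lo < 0) s_lo <- 0
  s_hi <- ri$high
  hi_closed <- FALSE
  if (record$test_type == "R" && s_hi > 1) {
    s_hi <- 1
    hi_closed <- TRUE  # |r| = 1 itself is attainable
  }
  p_hi <- .compute_p_record(record, stat_value = s_lo, tails = tails)
  p_lo <- .compute_p_record(record, stat_value = s_hi, tails = tails)
  if (p_lo == p_hi) return(p_interval(p_lo, p_hi))  # underflow collapse
  p_interval(p_lo, p_hi, lower_closed = hi_closed, upper_closed = lo_closed)
}

#' Interval of p-values compatible with a reported p clause
#'
#' `p = v` stands for the rounding interval of `v` at its printed precision
#' (so `p = .000` means `[0, .0005)`); `p < v` for `[0, v)`; `p > v` for
#' `(v, 1]`; `ns` for all nonsignificant values `(alpha, 1]`.
#'
#' @param p_comparator `"EQ"`, `"LT"`, `"GT"` or `"NS"`.
#' @param p_value printed p (ignored for NS).
#' @param p_decimals printed decimal digits (EQ only).
#' @param alpha significance level (NS only).
#' @return a [p_interval].
#' @export
reported_p_interval <- function(p_comparator, p_value = NA_real_,
                                p_decimals = NA_integer_, alpha = 0.05) {
  switch(
    p_comparator,
    EQ = {
      ri <- rounding_interval(p_value, p_decimals)
      lo <- max(ri$low, 0)
      if (ri$high > 1) p_interval(lo, 1, TRUE, TRUE)
      else p_interval(lo, ri$high, TRUE, FALSE)
    },
    LT = if (p_value == 0) p_interval(0, 0)
         else p_interval(0, p_value, TRUE, FALSE),
    GT = if (p_value == 1) p_interval(1, 1)
         else p_interval(p_value, 1, FALSE, TRUE),
    NS = p_interval(alpha, 1, FALSE, TRUE),
    stop("unknown p comparator: ", p_comparator, call. = FALSE)
  )
}

# Significance of the reported p clause, judged from the printed comparator
# and value: the printed claim "p = .05" is a claim of significance under
# the p_equal_alpha_sig convention even though its rounding interval
# straddles alpha. Returns "sig", "nonsig" or "straddle" (indeterminate).
.reported_significance <- function(p_comparator, p_value, alpha, eq_sig) {
  switch(
    p_comparator,
    EQ = if (if (eq_sig) p_value <= alpha else p_value < alpha)
           "sig" else "nonsig",
    LT = if (p_value <= alpha) "sig" else "straddle",
    GT = if (p_value >= alpha) "nonsig" else "straddle",
    NS = "nonsig"
  )
}

# Significance of a computed p interval: "sig" if entirely within the
# significant region, "nonsig" if entirely outside it, else "straddle".
.computed_significance <- function(iv, alpha, eq_sig) {
  if (eq_sig) {
    if (iv$upper < alpha || iv$upper == alpha) return("sig")
    if (iv$lower > alpha || (iv$lower == alpha && !iv$lower_closed))
      return("nonsig")
  } else {
    if (iv$upper < alpha || (iv$upper == alpha && !iv$upper_closed))
      return("sig")
    if (iv$lower >= alpha) return("nonsig")
  }
  "straddle"
}

#' Classify one extracted statistic as consistent or (grossly) inconsistent
#'
#' Implements the rounding-aware comparison: the result is consistent when
#' the interval of p-values attainable from the printed statistic overlaps
#' the interval compatible with the reported p clause. If the two-tailed
#' check fails, the document contains one-tailed language, and the family is
#' sign-symmetric (t, Z, r), the check is repeated with the one-tailed
#' recomputation and a success is recorded as `one_tailed_applied`. An
#' inconsistency is gross when the reported and recomputed significance at
#' `alpha` disagree outright (neither side indeterminate). For statistics
#' reported as a bound (`t(28) > 2.0`), only gross inconsistencies are
#' assessable.
#'
#' @param record one extracted statistic row from [find_statistics()].
#' @param config a [consist_config()].
#' @return list with elements `consistent`, `gross`, `one_tailed_applied`,
#'   `computed_p` (point recomputation at the printed statistic, with the
#'   tails that produced the final classification), `computed_interval`
#'   (a [p_interval]), `reported_interval`, and `alpha_used`.
#' @examples
#' rec <- find_statistics("t(28) = 2.14, p = .04")
#' check_consistency(rec[1, ])$consistent  # TRUE
#' @export
check_consistency <- function(record, config = consist_config()) {
  alpha <- config$alpha
  eq_sig <- config$p_equal_alpha_sig
  rep_iv <- reported_p_interval(record$p_comparator, record$p_value,
                                record$p_decimals, alpha)
  one_ok <- config$one_tailed_txt &&
    isTRUE(record$one_tailed_context) &&
    record$test_type %in% .symmetric_families
  one_tailed_applied <- FALSE
  tails_used <- "two"

  if (record$stat_comparator == "EQ") {
    comp_iv <- computed_p_interval(record, tails = "two")
    consistent <- interval_overlap(comp_iv, rep_iv)
    if (!consistent && one_ok) {
      comp_one <- computed_p_interval(record, tails = "one")
      if (interval_overlap(comp_one, rep_iv)) {
        consistent <- TRUE
        one_tailed_applied <- TRUE
        tails_used <- "one"
        comp_iv <- comp_one
      }
    }
    gross <- FALSE
    if (!consistent) {
      rs <- .reported_significance(record$p_comparator, record$p_value,
                                   alpha, eq_sig)
      cs <- .computed_significance(comp_iv, alpha, eq_sig)
      gross <- rs != "straddle" && cs != "straddle" && rs != cs
    }
  } else {
    # The printed statistic is only a bound, so the recomputed p is only
    # bounded on one side; plain inconsistencies cannot be assessed.
    bound_iv <- function(tails) {
      pb <- .compute_p_record(record, tails = tails)
      if (record$stat_comparator == "GT") {
        if (pb == 0) p_interval(0, 0) else p_interval(0, pb, TRUE, FALSE)
      } else {
        if (pb == 1) p_interval(1, 1) else p_interval(pb, 1, FALSE, TRUE)
      }
    }
    comp_iv <- bound_iv("two")
    rs <- .reported_significance(record$p_comparator, record$p_value,
                                 alpha, eq_sig)
    cs <- .computed_significance(comp_iv, alpha, eq_sig)
    gross <- rs != "straddle" && cs != "straddle" && rs != cs
    if (gross && one_ok) {
      comp_one <- bound_iv("one")
      cs1 <- .computed_significance(comp_one, alpha, eq_sig)
      if (!(cs1 != "straddle" && rs != "straddle" && cs1 != rs)) {
        gross <- FALSE
        one_tailed_applied <- TRUE
        tails_used <- "one"
        comp_iv <- comp_one
      }
    }
    consistent <- !gross
  }

  computed_p <- .compute_p_record(record, tails = tails_used)
  list(consistent = consistent, gross = gross,
       one_tailed_applied = one_tailed_applied,
       computed_p = computed_p, computed_interval = comp_iv,
       reported_interval = rep_iv, alpha_used = alpha)
}

#' Check a batch of extracted statistics
#'
#' Applies [check_consistency()] to every row; a per-record failure (a
#' domain error in the recomputation) is caught, reported via [message()],
#' and recorded in the `check_error` column while the batch continues.
#'
#' @param records data.frame from [find_statistics()].
#' @param config a [consist_config()].
#' @return `records` with appended columns `computed_p`, `computed_lower`,
#'   `computed_upper`, `consistent`, `gross`, `one_tailed_applied`,
#'   `alpha_used`, `check_error`.
#' @export
check_records <- function(records, config = consist_config()) {
  n <- nrow(records)
  out <- data.frame(computed_p = numeric(n), computed_lower = numeric(n),
                    computed_upper = numeric(n), consistent = logical(n),
                    gross = logical(n), one_tailed_applied = logical(n),
                    alpha_used = numeric(n), check_error = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- tryCatch(check_consistency(records[i, ], config),
                  error = function(e) e)
    if (inherits(v, "error")) {
      message("statconsist: cannot check '", records$raw_text[i], "': ",
              conditionMessage(v))
      out[i, ] <- list(NA_real_, NA_real_, NA_real_, NA, NA, NA,
                       config$alpha, conditionMessage(v))
    } else {
      out[i, ] <- list(v$computed_p, v$computed_interval$lower,
                       v$computed_interval$upper, v$consistent, v$gross,
                       v$one_tailed_applied, v$alpha_used, "")
    }
  }
  cbind(records, out)
}
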