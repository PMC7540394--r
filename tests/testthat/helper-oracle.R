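# Independent brute-force oracle: tail probabilities by adaptive numerical
# integration of the density, never via the p*() distribution functions the
# implementation uses.

oracle_p <- function(family, df1 = NA, df2 = NA, x, tails = "two") {
  tail_area <- function(dens, from) {
    if (!is.finite(from)) return(0)
    stats::integrate(dens, lower = from, upper = Inf,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  p <- switch(
    family,
    T = {
      a <- tail_area(function(u) stats::dt(u, df1), abs(x))
      if (tails == "two") 2 * a else a
    },
    Z = {
      a <- tail_area(stats::dnorm, abs(x))
      if (tails == "two") 2 * a else a
    },
    R = {
      if (abs(x) >= 1) return(0)
      tstat <- x * sqrt(df1 / (1 - x^2))
      a <- tail_area(function(u) stats::dt(u, df1), abs(tstat))
      if (tails == "two") 2 * a else a
    },
    F = tail_area(function(u) stats::df(u, df1, df2), x),
    CHI2 = , Q = , QW = , QB =
      tail_area(function(u) stats::dchisq(u, df1), x)
  )
  min(max(p, 0), 1)
}

# round half away from zero, as print formatting does
rhu <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

# build a one-row extracted-statistic record without going through the
# grammar, for unit-testing the downstream modules
make_record <- function(test_type, df1 = NA_real_, df2 = NA_real_,
                        stat_value, stat_decimals = 2L,
                        stat_comparator = "EQ", p_comparator = "EQ",
                        p_value = NA_real_, p_decimals = NA_integer_,
                        one_tailed_context = FALSE, source_id = "unit") {
  data.frame(source_id = source_id,
             raw_text = sprintf("%s = %s", test_type, stat_value),
             test_type = test_type, df1 = df1, df2 = df2,
             reported_n = NA_integer_, stat_comparator = stat_comparator,
             stat_value = stat_value, stat_decimals = stat_decimals,
             p_comparator = p_comparator, p_value = p_value,
             p_decimals = p_decimals,
             one_tailed_context = one_tailed_context, offset = 1L,
             stringsAsFactors = FALSE)
}

# random (family, dfs, statistic) triples spread across the tail range
random_triples <- function(n) {
  fams <- sample(c("T", "F", "CHI2", "Z", "R", "Q", "QW", "QB"), n,
                 replace = TRUE)
  lapply(seq_len(n), function(i) {
    fam <- fams[i]
    df1 <- switch(fam, T = , R = sample(3:200, 1), F = sample(1:10, 1),
                  Z = NA_real_, sample(1:30, 1))
    df2 <- if (fam == "F") sample(5:200, 1) else NA_real_
    x <- switch(fam,
                T = stats::runif(1, -5, 5),
                Z = stats::runif(1, -4, 4),
                R = stats::runif(1, -0.95, 0.95),
                F = stats::runif(1, 0, 8),
                stats::runif(1, 0, df1 + 4 * sqrt(2 * df1)))
    list(family = fam, df1 = df1, df2 = df2, x = x)
  })
}
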