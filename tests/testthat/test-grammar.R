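test_that("the canonical APA forms parse into fully populated records", {
  r <- find_statistics("APA style (e.g., t(28) = 2.14, p = .04)")
  expect_equal(nrow(r), 1L)
  expect_equal(r$test_type, "T")
  expect_equal(r$df1, 28)
  expect_equal(r$stat_comparator, "EQ")
  expect_equal(r$stat_value, 2.14)
  expect_equal(r$stat_decimals, 2L)
  expect_equal(r$p_comparator, "EQ")
  expect_equal(r$p_value, 0.04)
  expect_equal(r$p_decimals, 2L)

  q <- find_statistics("Qb(1) = 3.78, p < .05")
  expect_equal(q$test_type, "QB")
  expect_equal(q$df1, 1)
  expect_equal(q$stat_value, 3.78)
  expect_equal(q$p_comparator, "LT")
  expect_equal(q$p_value, 0.05)

  expect_equal(nrow(find_statistics("the mean was 2.14 (SD = 0.3)")), 0L)

  two <- find_statistics(
    "F(2, 30) = 4.50, p < .05 ... r(28) = .35, p = .06")
  expect_equal(two$test_type, c("F", "R"))
  expect_equal(two$df1, c(2, 28))
  expect_equal(two$df2, c(30, NA))
  expect_equal(two$stat_value, c(4.5, 0.35))
})

test_that("symbol spelling, case and subscript variants map to one family", {
  chi <- c("χ2(1) = 3.84, p = .05", "X2(1) = 3.84, p = .05",
           "x2(1) = 3.84, p = .05", "chi2(1) = 3.84, p = .05")
  for (s in chi) {
    r <- find_statistics(s)
    expect_equal(r$test_type, "CHI2", label = s)
    expect_equal(r$df1, 1)
  }
  rn <- find_statistics("χ2(2, N = 170) = 14.14, p < .001")
  expect_equal(rn$test_type, "CHI2")
  expect_equal(rn$reported_n, 170L)
  expect_equal(rn$df1, 2)

  for (s in c("Qw(3) = 9.1, p = .03", "Q_w(3) = 9.1, p = .03",
              "Qwithin(3) = 9.1, p = .03", "Q-within(3) = 9.1, p = .03"))
    expect_equal(find_statistics(s)$test_type, "QW", label = s)
  for (s in c("Qb(3) = 9.1, p = .03", "Q_b(3) = 9.1, p = .03",
              "Qbetween(3) = 9.1, p = .03"))
    expect_equal(find_statistics(s)$test_type, "QB", label = s)
  expect_equal(find_statistics("Q(3) = 9.1, p = .03")$test_type, "Q")
  # unsupported subscripts are not silently folded into a Q family
  expect_equal(nrow(find_statistics("Q_total(3) = 9.1, p = .03")), 0L)

  expect_equal(find_statistics("Z = 2.58, p = .01")$test_type, "Z")
  expect_equal(find_statistics("z = -1.20, p = .23")$stat_value, -1.2)
  # APA case: uppercase T / lowercase f are not statistics
  expect_equal(nrow(find_statistics("T(28) = 2.14, p = .04")), 0L)
  expect_equal(nrow(find_statistics("f(2, 30) = 4.50, p = .05")), 0L)
})

test_that("comparators, p spellings and decimal forms are tolerated", {
  expect_equal(find_statistics("t(28) = 2.14, p ≤ .04")$p_comparator, "LT")
  expect_equal(find_statistics("t(28) ≥ 2.14, p = .04")$stat_comparator,
               "GT")
  expect_equal(find_statistics("t(28) = 2.14, P = 0.04")$p_value, 0.04)
  expect_equal(find_statistics("t(28) = 2.14, p-value = .04")$p_value, 0.04)
  expect_equal(find_statistics("t(28) = 2.14, p=.04")$p_value, 0.04)
  ns <- find_statistics("t(28) = 1.10, ns")
  expect_equal(ns$p_comparator, "NS")
  expect_true(is.na(ns$p_value))
  expect_equal(find_statistics("t(28) = 1.10, n.s.")$p_comparator, "NS")
  # Welch-style decimal dfs
  w <- find_statistics("t(26.4) = 2.10, p = .045")
  expect_equal(w$df1, 26.4)
  expect_equal(w$p_decimals, 3L)
  # p = .000 keeps its printed precision for interval semantics
  z <- find_statistics("t(28) = 9.99, p = .000")
  expect_equal(z$p_value, 0)
  expect_equal(z$p_decimals, 3L)
})

test_that("malformed numerics are skipped with a log message, not an error", {
  expect_message(r <- find_statistics("χ2(1) = -3.84, p = .05"),
                 "negative statistic")
  expect_equal(nrow(r), 0L)
  expect_message(r2 <- find_statistics("r(28) = 1.35, p = .06"),
                 "correlation")
  expect_equal(nrow(r2), 0L)
  expect_message(r3 <- find_statistics("t(0) = 2.14, p = .04"),
                 "degrees of freedom")
  expect_equal(nrow(r3), 0L)
  expect_message(r4 <- find_statistics("t(28) = 2.14, p = 1.4"),
                 "outside")
  expect_equal(nrow(r4), 0L)
  # negative t is legitimate, sign retained
  expect_equal(find_statistics("t(28) = -2.14, p = .04")$stat_value, -2.14)
})

test_that("one-tailed language is detected document-wide", {
  expect_true(detect_one_tailed_language("a one-tailed test was used"))
  expect_true(detect_one_tailed_language("a one tailed test"))
  expect_true(detect_one_tailed_language("one sided hypotheses"))
  expect_true(detect_one_tailed_language("the DIRECTIONAL hypothesis"))
  expect_false(detect_one_tailed_language("we used two-tailed tests throughout"))
  txt <- "Intro one-sided note. Then t(28) = 2.14, p = .04."
  expect_true(all(find_statistics(txt)$one_tailed_context))
  expect_false(any(find_statistics("t(28) = 2.14, p = .04")$one_tailed_context))
})

test_that("rendered synthetic cases round-trip through the grammar", {
  spec <- corpus_spec(seed = 2024)
  set.seed(spec$seed)
  labels <- sample(c("CONSISTENT", "INCONSISTENCY", "GROSS"), 1000,
                   replace = TRUE, prob = c(0.6, 0.25, 0.15))
  cases <- lapply(labels, function(l) generate_case(spec, label = l))
  recs <- lapply(cases, function(cs) find_statistics(cs$apa))
  expect_true(all(vapply(recs, nrow, integer(1)) == 1L))
  recs <- do.call(rbind, recs)
  expect_equal(recs$test_type, vapply(cases, `[[`, character(1), "test_type"))
  expect_equal(recs$df1, vapply(cases, `[[`, numeric(1), "df1"))
  expect_equal(recs$df2, vapply(cases, `[[`, numeric(1), "df2"))
  expect_equal(recs$stat_value, vapply(cases, `[[`, numeric(1), "stat_value"))
  expect_equal(recs$p_comparator,
               vapply(cases, `[[`, character(1), "p_comparator"))
  expect_equal(recs$p_value, vapply(cases, `[[`, numeric(1), "p_value"))
  expect_equal(recs$p_decimals,
               as.integer(vapply(cases, `[[`, numeric(1), "p_decimals")))
})

test_that("matches come in document order with disjoint spans", {
  set.seed(5)
  spec <- corpus_spec(seed = 5)
  cases <- lapply(1:8, function(i) generate_case(spec, label = "CONSISTENT"))
  txt <- render_document(cases, "txt")
  recs <- find_statistics(txt)
  expect_equal(nrow(recs), 8L)
  expect_true(all(diff(recs$offset) > 0))
  ends <- recs$offset + nchar(recs$raw_text) - 1L
  expect_true(all(recs$offset[-1] > ends[-length(ends)]))
})
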