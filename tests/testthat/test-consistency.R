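test_that("the computed p interval maps the statistic rounding interval", {
  # t(28) printed 2.14: p attainable between t = 2.145 (excluded) and
  # t = 2.135 (included); frozen endpoints from the integration oracle
  iv <- computed_p_interval(make_record("T", df1 = 28, stat_value = 2.14))
  expect_equal(iv$lower, 0.04077159, tolerance = 1e-6)
  expect_equal(iv$upper, 0.04165091, tolerance = 1e-6)
  expect_false(iv$lower_closed)
  expect_true(iv$upper_closed)
  expect_equal(iv$lower, oracle_p("T", df1 = 28, x = 2.145), tolerance = 1e-8)
  expect_equal(iv$upper, oracle_p("T", df1 = 28, x = 2.135), tolerance = 1e-8)

  qb <- computed_p_interval(make_record("QB", df1 = 1, stat_value = 3.78))
  expect_equal(qb$lower, 0.05171391, tolerance = 1e-6)
  expect_equal(qb$upper, 0.05202390, tolerance = 1e-6)

  # z printed 0.00: the magnitude's lower bound clamps to 0, so p reaches 1
  z0 <- computed_p_interval(make_record("Z", stat_value = 0))
  expect_equal(z0$upper, 1)
  expect_true(z0$upper_closed)

  # negative statistics use their magnitude
  expect_equal(computed_p_interval(make_record("T", df1 = 28,
                                               stat_value = -2.14)),
               computed_p_interval(make_record("T", df1 = 28,
                                               stat_value = 2.14)))
})

test_that("reported p clauses become the right probability intervals", {
  eq <- reported_p_interval("EQ", 0.04, 2L)
  expect_equal(eq$lower, 0.035, tolerance = 1e-12)
  expect_equal(eq$upper, 0.045, tolerance = 1e-12)
  expect_true(eq$lower_closed); expect_false(eq$upper_closed)

  lt <- reported_p_interval("LT", 0.05)
  expect_equal(c(lt$lower, lt$upper), c(0, 0.05))
  expect_true(lt$lower_closed); expect_false(lt$upper_closed)

  gt <- reported_p_interval("GT", 0.05)
  expect_equal(c(gt$lower, gt$upper), c(0.05, 1))
  expect_false(gt$lower_closed); expect_true(gt$upper_closed)

  ns <- reported_p_interval("NS", alpha = 0.05)
  expect_equal(c(ns$lower, ns$upper), c(0.05, 1))
  expect_false(ns$lower_closed)

  # "p = .000" means: rounds to zero at three decimals
  z <- reported_p_interval("EQ", 0, 3L)
  expect_equal(c(z$lower, z$upper), c(0, 0.0005))
  expect_true(z$lower_closed); expect_false(z$upper_closed)

  one <- reported_p_interval("EQ", 1, 2L)
  expect_equal(c(one$lower, one$upper), c(0.995, 1))
  expect_true(one$upper_closed)
})

test_that("worked examples classify as the algorithm prescribes", {
  v1 <- check_consistency(find_statistics("t(28) = 2.14, p = .04")[1, ])
  expect_true(v1$consistent)
  expect_false(v1$gross)
  expect_equal(round(v1$computed_p, 2), 0.04)

  v2 <- check_consistency(find_statistics("Qb(1) = 3.78, p < .05")[1, ])
  expect_false(v2$consistent)
  expect_true(v2$gross)          # computed tail > .05 but reported significant

  v3 <- check_consistency(find_statistics("t(28) = 2.14, p < .001")[1, ])
  expect_false(v3$consistent)    # reported bound excludes ~.041
  expect_false(v3$gross)         # but both sides agree it is significant

  rec <- find_statistics("one-tailed: t(28) = 1.80, p = .04")[1, ]
  v4 <- check_consistency(rec)
  expect_true(v4$consistent)
  expect_true(v4$one_tailed_applied)
  # identical record without the keyword stays inconsistent
  v5 <- check_consistency(find_statistics("t(28) = 1.80, p = .04")[1, ])
  expect_false(v5$consistent)
  expect_false(v5$one_tailed_applied)
  # the rescue can be disabled in configuration
  v6 <- check_consistency(rec, consist_config(one_tailed_txt = FALSE))
  expect_false(v6$consistent)
})

test_that("one-tailed rescue is confined to t, Z and r", {
  # chi-squared has no tail to halve: keyword must not rescue it
  rec <- find_statistics("one-tailed: χ2(1) = 3.78, p = .026")[1, ]
  v <- check_consistency(rec)
  expect_false(v$consistent)
  expect_false(v$one_tailed_applied)
})

test_that("records printed from their own recomputed p are always consistent", {
  set.seed(99)
  for (tr in random_triples(1000)) {
    sv <- rhu(tr$x, 2)
    if (tr$family == "R" && abs(sv) > 1) next
    rec <- make_record(tr$family, df1 = tr$df1, df2 = tr$df2,
                       stat_value = sv, stat_decimals = 2L)
    p <- compute_p(tr$family, df1 = tr$df1, df2 = tr$df2, stat_value = sv)
    dec <- sample(2:4, 1)
    rec$p_value <- rhu(p, dec)
    rec$p_decimals <- dec
    v <- check_consistency(rec)
    expect_true(v$consistent,
                label = sprintf("%s(%s,%s)=%s p=%s", tr$family, tr$df1,
                                tr$df2, sv, rec$p_value))
    expect_false(v$gross)
  }
})

test_that("a gross flag implies an inconsistency flag", {
  set.seed(123)
  spec <- corpus_spec(seed = 123)
  for (i in 1:300) {
    lbl <- sample(c("CONSISTENT", "INCONSISTENCY", "GROSS"), 1)
    cs <- generate_case(spec, label = lbl)
    v <- check_consistency(find_statistics(cs$apa)[1, ])
    expect_true(!v$gross || !v$consistent)
  }
})

test_that("significance at the reported boundary follows the alpha rule", {
  # t(28) = 1.80 has recomputed p ~ .083; reporting "p = .05" claims
  # significance under the default boundary rule, so the mismatch is gross
  rec <- find_statistics("t(28) = 1.80, p = .05")[1, ]
  v_on <- check_consistency(rec)
  expect_false(v_on$consistent)
  expect_true(v_on$gross)
  v_off <- check_consistency(rec, consist_config(p_equal_alpha_sig = FALSE))
  expect_false(v_off$consistent)
  expect_false(v_off$gross)   # p = .05 now counts as nonsignificant too
})

test_that("statistics reported as bounds only yield gross verdicts", {
  # "F(2, 30) > 4.5" pins p below ~.0199: reporting nonsignificance is a
  # decision error, but a compatible p cannot be flagged at all
  g <- check_consistency(find_statistics("F(2, 30) > 4.50, p > .5")[1, ])
  expect_true(g$gross)
  expect_false(g$consistent)
  ok <- check_consistency(find_statistics("F(2, 30) > 4.50, p < .05")[1, ])
  expect_true(ok$consistent)
  expect_false(ok$gross)
  # p < .2 straddles alpha on the reported side: indeterminate, not gross
  nd <- check_consistency(find_statistics("F(2, 30) > 4.50, p > .02")[1, ])
  expect_false(nd$gross)
})

test_that("ns reports are judged against the nonsignificant region", {
  v <- check_consistency(find_statistics("t(28) = 3.50, ns")[1, ])
  expect_false(v$consistent)  # p ~ .0016 is firmly significant
  expect_true(v$gross)
  v2 <- check_consistency(find_statistics("t(28) = 1.10, ns")[1, ])
  expect_true(v2$consistent)  # p ~ .28
})

test_that("batch checking isolates per-record failures", {
  recs <- rbind(make_record("T", df1 = 28, stat_value = 2.14,
                            p_value = 0.04, p_decimals = 2L),
                make_record("F", df1 = 2, df2 = NA_real_, stat_value = 4.5,
                            p_value = 0.01, p_decimals = 2L))
  expect_message(out <- check_records(recs), "cannot check")
  expect_equal(nrow(out), 2L)
  expect_equal(out$check_error[1], "")
  expect_match(out$check_error[2], "df2")
  expect_true(is.na(out$consistent[2]))
  expect_false(is.na(out$computed_p[1]))
})
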