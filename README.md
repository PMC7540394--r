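# statconsist

Automated detection of statistical reporting inconsistencies in
scientific articles, aimed at meta-analysts, journal editors and authors
who want to double-check results before relying on them. An APA-style
test report — `t(28) = 2.14, p = .04` — is internally redundant: the
p-value can be recomputed from the statistic and its degrees of freedom.
`statconsist` extracts every such result from plain text, HTML or
text-based PDF articles, recomputes the p-value, and flags

* an **inconsistency** (`error`) when the reported p cannot be obtained
  from any unrounded statistic compatible with the printed one, and
* a **gross inconsistency** (`decision_error`) when, additionally, the
  reported and recomputed p fall on opposite sides of α, so the
  significance conclusion itself changes.

## The check

For a statistic x with degrees of freedom ν the recomputed p is the
reference-distribution tail: p = 2·P(T_ν ≥ |x|) for t (halved for a
one-tailed test), 2·P(N(0,1) ≥ |x|) for Z, P(F_{ν1,ν2} ≥ x) for F, and
P(χ²_ν ≥ x) for χ² and the meta-analytic heterogeneity tests Q, Q_w and
Q_b, which follow a χ² distribution. Correlations are transformed via
t = r·sqrt(ν/(1−r²)). Comparison is rounding-aware on both sides: a
statistic printed 2.5 stands for the interval [2.45, 2.55), a reported
`p = .04` for [.035, .045), and the result is consistent when the induced
p intervals overlap. If the document says "one-tailed", "one-sided" or
"directional" anywhere, a failing t/Z/r check is retried with the halved
recomputation. The default α of .05 and the boundary convention
(`p = .05` counts as significant) are configurable.

## Worked example

```r
library(statconsist)
run_check(c("t(28) = 2.14, p = .04", "Qb(1) = 3.78, p < .05"))
#>       source                   raw test_type df1 df2 reported_p   computed
#> 1 text-input t(28) = 2.14, p = .04         T  28  NA      = .04 0.04120916
#> 2 text-input Qb(1) = 3.78, p < .05        QB   1  NA      < .05 0.05186866
#>   error decision_error one_tailed_applied
#> 1 FALSE          FALSE              FALSE
#> 2  TRUE           TRUE              FALSE
```

The t test recomputes to p = 0.0412, which rounds to the reported .04:
consistent. The Q-between test recomputes to p = 0.0519 — every statistic
rounding to 3.78 stays above .05 — while the author claims `p < .05`, so
the result is not just inconsistent but a decision error.

Whole files and directories work the same way (`run_check("papers/")`),
as does the command line:

```sh
echo "one-sided test: t(28) = 1.80, p = .04" | exec/statconsist check -
```

Here the two-tailed recomputation (p = .083) contradicts the report, but
the document announces one-sided testing and the halved p = .041 rounds
to .04, so the row comes back consistent with `one_tailed_applied = TRUE`.
Use `--output results.csv` for a CSV report, `--alpha`, `--recursive` and
`--no-one-tailed-txt` to adjust the run.

Validation utilities are included: `generate_corpus()` builds a seeded
synthetic corpus of prose documents with planted results whose
consistency labels are known by construction, and `evaluate_detection()`
scores sensitivity and specificity against that ground truth.

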