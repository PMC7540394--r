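---
title: "Rounding-aware consistency checking of reported significance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rounding-aware consistency checking of reported significance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statconsist)
```

## The problem

A null-hypothesis significance test reported in APA style carries three
redundant numbers: a test statistic, its degrees of freedom, and a p-value.
The redundancy makes the triplet checkable — the p-value can be recomputed
from the other two — and published articles fail this check surprisingly
often. A mismatch ("inconsistency") may be a typo with no consequence, or
it may flip the significance conclusion ("gross inconsistency"), in which
case any downstream use of the result — including effect sizes computed
from the test statistic for a meta-analysis — inherits the error.

`statconsist` automates the check in four steps: convert a document to
plain text, extract APA-style results with a pattern grammar, recompute
each p-value, and compare reported against recomputed values under
rounding-interval semantics.

## Recomputation model

For a statistic $x$ with degrees of freedom $\nu$ the recomputed p-value
is the tail probability of the reference distribution:

* $t$: $p = 2\,P(T_\nu \ge |x|)$, two-tailed by default;
* $Z$: $p = 2\,P(N(0,1) \ge |x|)$;
* $r$: transformed to $t = r\sqrt{\nu/(1-r^2)}$ and treated as a $t$ test
  with the reported $\nu$ (APA prints $\nu = n-2$ for correlations; the
  sample size itself is not reconstructed);
* $F$: $p = P(F_{\nu_1,\nu_2} \ge x)$, upper tail only;
* $\chi^2$ and the meta-analytic heterogeneity tests $Q$, $Q_w$, $Q_b$,
  which all follow a $\chi^2$ distribution: $p = P(\chi^2_\nu \ge x)$.

Non-integer degrees of freedom (Welch or sphericity-corrected) are passed
to the continuous distribution functions unmodified. One-tailed
recomputation, which exactly halves the two-tailed p for the symmetric
families $t$, $Z$, $r$, is never the default: it is a conditional
correction, described below.

## Rounding-interval semantics

A printed number stands for an interval of unrounded values. Under
half-up rounding, a statistic printed as 2.5 could have been anything in
$[2.45, 2.55)$ — of which 2.54 is the largest two-decimal member — and a
p-value printed as .04 could be anything in $[.035, .045)$. The package
represents both sides as probability intervals with explicit endpoint
inclusivity:

* the **computed interval** maps the statistic's rounding interval
  through the tail function; monotonicity means only the endpoints need
  evaluating. The lower p endpoint is open (it comes from the excluded
  upper statistic bound), the upper closed. Bounds falling outside the
  statistic's domain are clamped — a $z$ printed 0.00 yields an interval
  reaching $p = 1$ inclusive.
* the **reported interval** is the rounding interval for `p = v`
  (so `p = .000` naturally denotes $[0, .0005)$ with no special casing),
  $[0, v)$ for `p < v`, $(v, 1]$ for `p > v`, and $(\alpha, 1]$ for a
  bare "ns".

A record is **consistent** when the two intervals share at least one
point, including a single touching endpoint if that point belongs to both.
Where tail probabilities underflow double precision the computed interval
collapses to a point and is treated as closed.

The choice of half-open $[{\rm low}, {\rm high})$ source intervals is a
convention: a value exactly halfway could round either way in real
typesetting. We adopt half-up uniformly because it is deterministic and
reproduces the conventional printed endpoints (2.45 and 2.54 above). The
continuous upper endpoint 2.55 is excluded; an enumeration at two decimals
reads the same interval as "2.45 to 2.54".

## The one-tailed rule

If a document contains the words "one-tailed", "one-sided" (hyphen or
space) or "directional" anywhere in its text — the search is
document-global, not per-sentence — every extracted statistic carries a
one-tailed context flag. When the two-tailed check fails for a flagged
$t$, $Z$ or $r$ record, the check is repeated with the halved
recomputation; success rescues the record as consistent and is reported
as `one_tailed_applied`. The rule is deliberately conditional and
conservative: it never penalises a result that was consistent two-tailed,
and it never applies to the inherently one-sided families.

## Gross inconsistencies and the significance boundary

An inconsistency is **gross** when the reported and recomputed
significance at level $\alpha$ (default 0.05) disagree outright. The two
sides are judged asymmetrically, on purpose:

* the *computed* side uses the full computed interval: entirely inside
  the significant region, entirely outside, or straddling. A straddling
  interval is indeterminate and can never support a gross flag.
* the *reported* side uses the printed claim itself: `p = .05` is read as
  a claim of significance (configurable via `p_equal_alpha_sig`), even
  though its rounding interval $[.045, .055)$ straddles $\alpha$ — the
  author asserting `p = .05` is asserting a significant result under the
  inclusive convention. `p < v` claims significance when $v \le \alpha$;
  `p > v` claims nonsignificance when $v \ge \alpha$; `ns` always claims
  nonsignificance; anything else is indeterminate.

Judging the reported side from the interval instead would make a reported
`p = .05` unclassifiable, which contradicts how such claims are read in
practice; this asymmetry is the package's resolution of that tension.

Statistics reported only as bounds (`F(2, 30) > 4.50`) pin the recomputed
p on one side only, so plain inconsistencies are not assessable and not
flagged; a gross contradiction (a bound proving significance while the
author reports nonsignificance, or vice versa) still is.

Legitimate corrections are a known source of flags: a
Bonferroni-multiplied p-value or sphericity-corrected degrees of freedom
paired with an uncorrected statistic are internally inconsistent and will
be flagged as such. The package does not attempt to detect or undo
corrections; authors should report the fully adjusted triplet (or adjust
$\alpha$ rather than the p-value).

## The pattern grammar

The grammar matches `SYMBOL [ (df[, df2 | , N = n]) ] CMP value, p CMP
value` with the comparators `=`, `<`, `>` (`≤`/`≥` normalised to the
strict forms) and an `ns`/`n.s.` alternative for the p clause. Symbol
case follows APA: lower-case `t`/`r`, upper-case `F`/`Q`, `Z` in either
case, and the chi-squared symbol in the spellings `χ2`, `Χ2`, `X2`, `x2`,
`chi2` that survive format conversion. `Q` subscripts map `Qw`, `Q_w`,
`Q-within`, `Qwithin` (and the `between` counterparts) onto the
within/between families; unknown subscripts such as `Q_total` are not
matched. A `Z` takes no parenthesised degrees of freedom — a df-bearing Z
is rejected rather than guessed at. Degrees of freedom may be decimal but
must be positive; `t`, `Z`, `r` may be negative; a negative `F`, `χ2` or
`Q` fails the family's domain and the span is skipped with a log message,
as are `|r| > 1` and `p > 1`. Matches are returned in document order with
pairwise-disjoint spans.

Results with a bare `ns` are extracted and checked against the
nonsignificant region $(\alpha, 1]$. This is a deliberate extension
beyond the minimal grammar — `ns` reports are common and checkable — but
it is worth knowing when comparing counts with other tools.

Statistics in tables are out of scope: tables typically factor the
degrees of freedom out into the caption, leaving nothing recognisable
next to each entry. Effect sizes and non-APA national styles are also out
of scope.

## Document ingestion

All input is normalised before extraction: unicode NFKC (flattening
superscripts, ligatures and italic mathematical letters, so `χ²` becomes
`χ2` and an italic `𝑝` becomes `p`), an explicit map for dash and quote
look-alikes, removal of control characters, and collapsing of horizontal
whitespace. Normalisation is idempotent. HTML is converted with a
depth-first walk that drops scripts and styles, flattens inline markup
(`<i>t</i>(28)` → `t(28)`) and inserts line breaks at block boundaries so
adjacent cells or paragraphs cannot fuse into one token. HTML is the
preferred input: PDF-to-text conversion is inherently less reliable.

PDF support is a minimal extractor for text-based PDFs written for this
package: it locates content streams (honouring the dictionary `/Length`),
inflates `FlateDecode` streams, collects literal text-showing operators,
treats positioning operators as line breaks, rejoins words hyphenated at
line breaks, and restricts itself to ASCII text. Encrypted and image-only
PDFs raise conversion errors; undecodable streams are recorded as
warnings. Scanned PDFs, hex-string text and CID fonts are out of scope.
The matching fixture writer produces single-page PDFs from text, so the
round-trip is exercised in tests without any binary fixtures.

## The synthetic corpus

Real validation corpora for this task are manually coded articles; the
package instead ships a generator whose ground truth is known by
construction. Every case starts from an unrounded true statistic drawn by
inverting a uniformly drawn true p in $[0.002, 0.98]$ (avoiding
$\alpha \pm 0.002$ so labels stay robust at the boundary), printed at two
decimals. Then:

* a **consistent** case reports the correctly rounded true p (at 2–3
  decimals, occasionally as a correct `<` bound). Both intervals contain
  the true p, so they must overlap — no checker involved.
* a planted **inconsistency** first requires the computed interval to sit
  cleanly on one side of $\alpha$ (margin 0.001, re-drawn otherwise),
  then reports a 3-decimal p whose rounding interval is disjoint from the
  computed interval but on the same side of $\alpha$.
* a planted **gross inconsistency** reports from the opposite side of
  $\alpha$, as a disjoint 3-decimal value or as a `p < .05` / `p > .05`
  bound.

About 15% of documents carry one-tailed language. Cases in such documents
are constrained so the rescue rule cannot silently change their label:
consistent cases may print the halved p (exercising the rescue), while
planted inconsistencies must also be disjoint from the halved interval.
Truth labels are verified in the test suite by interval logic rebuilt
from scratch on top of a numerical-integration oracle, not by the engine
being tested.

The default corpus — 500 documents with 4 statistics each, total
inconsistency rate 0.3 of which gross 0.1, families drawn uniformly with
field-typical degrees of freedom (t: 5–200, F: 1–8 over 10–120,
χ²/Q: 1–30, r: 10–150) — is the problem size used for end-to-end
validation, where the pipeline is expected to recover every planted label
from both TXT and HTML renderings. Because the generator and the grammar
share one dialect of APA by construction, any miss there is a bug, and
perfect recovery says nothing about recall on real articles with
typesetting noise, tables, or deviant reporting styles. What the
synthetic study does transfer is the arithmetic: rounding intervals,
tail recomputation and the classification rules are exactly those applied
to real documents.

## Numerical choices

* Tail probabilities come from R's distribution functions; the test suite
  pins them to an independent adaptive-integration oracle at $10^{-8}$.
* Half-up rounding is implemented as
  $\mathrm{sign}(x)\lfloor |x| 10^d + 0.5\rfloor / 10^d$; printed-number
  comparisons in tests allow for binary representation at $10^{-12}$.
* Interval overlap at a shared endpoint counts only if the point belongs
  to both intervals.
* Generator retries are bounded (100 draws) and a failure to place a
  label is an error, never a silent label change.
* Batch checking isolates per-record domain errors into a `check_error`
  column rather than aborting the run.

## Known limitations

Only APA-style full-text reporting is recognised; recall on real
articles is bounded by typesetting quality, especially for PDFs. The
one-tailed flag is document-global, so a single phrase can rescue any
symmetric-family record in the document. Corrections (Bonferroni,
sphericity) are flagged, not detected. The empirical prevalence of
inconsistencies in any given literature cannot be inferred from the
synthetic corpus, whose rates are set by specification.
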