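Package: statconsist
Title: Detect Statistical Reporting Inconsistencies in Scientific Articles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts null-hypothesis significance test results reported in
    APA style (t, F, r, Z, chi-squared, and meta-analytic Q tests) from plain
    text, HTML, or PDF articles, recomputes each p-value from the reported
    test statistic and degrees of freedom, and flags results whose reported
    p-value is inconsistent with the recomputation after allowing for
    rounding, including gross inconsistencies where the significance
    conclusion itself changes. Includes a seeded synthetic-corpus generator
    with constructively known ground-truth labels for validating detection
    sensitivity and specificity, batch directory checking, and CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    stringi
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
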