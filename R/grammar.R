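# Pattern grammar for APA-style NHST results.
#
# A result has the shape
#   SYMBOL [ "(" df [", " df2 | ", N = " n] ")" ] CMP value ", p" CMP value
# with SYMBOL one of t, F, r, Z/z, chi-squared (several spellings), Q, Qw,
# Qb. The trailing p clause may instead be "ns"/"n.s." (reported
# nonsignificant without a number). Case is significant: APA prescribes
# lower-case t/r and upper-case F/Q; Z is tolerated in both cases; the
# chi-squared symbol survives PDF conversion in several spellings.

.re_num  <- "(\\d+(?:\\.\\d+)?)"                      # df (nonnegative)
.re_sval <- "(-?(?:\\d+(?:\\.\\d+)?|\\.\\d+))"        # statistic value
.re_pval <- "(\\d+(?:\\.\\d+)?|\\.\\d+)"              # p value
.re_cmp  <- "([=<>\u2264\u2265])"
.re_lb   <- "(?<![A-Za-z0-9_.])"                      # symbol boundary
.re_ptail <- paste0(
  ",\\s*(?:[pP](?:[- ]?value)?\\s*", .re_cmp, "\\s*", .re_pval,
  "|(ns|n\\.s\\.))")

# group layout after the symbol: df1? df2/N? scmp sval pcmp pval ns
.grammar <- list(
  T = list(type = "T", n_df = 1L,
           pattern = paste0(.re_lb, "t\\s*\\(\\s*", .re_num, "\\s*\\)\\s*",
                            .re_cmp, "\\s*", .re_sval, .re_ptail)),
  R = list(type = "R", n_df = 1L,
           pattern = paste0(.re_lb, "r\\s*\\(\\s*", .re_num, "\\s*\\)\\s*",
                            .re_cmp, "\\s*", .re_sval, .re_ptail)),
  F = list(type = "F", n_df = 2L,
           pattern = paste0(.re_lb, "F\\s*\\(\\s*", .re_num, "\\s*,\\s*",
                            .re_num, "\\s*\\)\\s*", .re_cmp, "\\s*",
                            .re_sval, .re_ptail)),
  CHI2 = list(type = "CHI2", n_df = 1L, has_n = TRUE,
              pattern = paste0(.re_lb, "(?:\u03c72|\u03a72|X2|x2|chi2)",
                               "\\s*\\(\\s*", .re_num,
                               "(?:\\s*,\\s*[Nn]\\s*=\\s*(\\d+))?\\s*\\)\\s*",
                               .re_cmp, "\\s*", .re_sval, .re_ptail)),
  Z = list(type = "Z", n_df = 0L,
           pattern = paste0(.re_lb, "[Zz]\\s*", .re_cmp, "\\s*", .re_sval,
                            .re_ptail)),
  QW = list(type = "QW", n_df = 1L,
            pattern = paste0(.re_lb, "Q(?:[-_]?within|_?w)\\s*\\(\\s*",
                             .re_num, "\\s*\\)\\s*", .re_cmp, "\\s*",
                             .re_sval, .re_ptail)),
  QB = list(type = "QB", n_df = 1L,
            pattern = paste0(.re_lb, "Q(?:[-_]?between|_?b)\\s*\\(\\s*",
                             .re_num, "\\s*\\)\\s*", .re_cmp, "\\s*",
                             .re_sval, .re_ptail)),
  Q = list(type = "Q", n_df = 1L,
           pattern = paste0(.re_lb, "Q\\s*\\(\\s*", .re_num, "\\s*\\)\\s*",
                            .re_cmp, "\\s*", .re_sval, .re_ptail))
)

.upper_tail_families <- c("F", "CHI2", "Q", "QW", "QB")
.symmetric_families <- c("T", "Z", "R")

.decimals_of <- function(s) {
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot == -1L) 0L else nchar(s) - dot
}

.map_cmp <- function(s) {
  switch(s, "=" = "EQ", "<" = "LT", ">" = "GT",
         "\u2264" = "LT", "\u2265" = "GT")
}

# all matches of one family pattern, with capture groups, as a data.frame
.family_matches <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  full <- regmatches(text, list(m))[[1]]
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  groups <- matrix(NA_character_, nrow = length(m), ncol = ncol(cs))
  for (j in seq_len(ncol(cs))) {
    hit <- cs[, j] > 0L
    if (!any(hit)) next
    groups[hit, j] <- substring(text, cs[hit, j], cs[hit, j] + cl[hit, j] - 1L)
  }
  list(start = as.integer(m), len = attr(m, "match.length"),
       raw = full, groups = groups)
}

.empty_records <- function() {
  data.frame(source_id = character(), raw_text = character(),
             test_type = character(), df1 = numeric(), df2 = numeric(),
             reported_n = integer(), stat_comparator = character(),
             stat_value = numeric(), stat_decimals = integer(),
             p_comparator = character(), p_value = numeric(),
             p_decimals = integer(), one_tailed_context = logical(),
             offset = integer(), stringsAsFactors = FALSE)
}

#' Extract APA-style NHST results from document text
#'
#' Scans normalized text for reported t, F, r, Z, chi-squared and
#' meta-analytic Q statistics (including the subgroup variants
#' \eqn{Q_w}/\eqn{Q_b}) with their degrees of freedom, comparator, value and
#' reported p. Matches are returned in document order with pairwise-disjoint
#' spans. A span whose symbol/df prefix matches but whose numbers violate
#' the family's constraints (negative F/chi-squared/Q, |r| > 1, p > 1,
#' nonpositive df) is skipped with a [message()].
#'
#' @param text a [document_text], or a character scalar (normalized
#'   automatically).
#' @return data.frame with one row per extracted statistic and columns
#'   `source_id`, `raw_text`, `test_type` (`T`, `F`, `CHI2`, `Z`, `R`, `Q`,
#'   `QW`, `QB`), `df1`, `df2`, `reported_n`, `stat_comparator`,
#'   `stat_value`, `stat_decimals`, `p_comparator` (`EQ`, `LT`, `GT`, `NS`),
#'   `p_value`, `p_decimals`, `one_tailed_context`, `offset`. Zero matches
#'   give a zero-row data.frame.
#' @export
find_statistics <- function(text) {
  doc <- as_document_text(text)
  txt <- doc$text
  one_tailed <- detect_one_tailed_language(doc)

  cand <- list()
  for (fam in .grammar) {
    fm <- .family_matches(txt, fam$pattern)
    if (is.null(fm)) next
    for (i in seq_along(fm$start)) {
      g <- fm$groups[i, ]
      k <- 0L
      df1 <- NA_real_; df2 <- NA_real_; rep_n <- NA_integer_
      if (fam$n_df >= 1L) { k <- k + 1L; df1 <- as.numeric(g[k]) }
      if (fam$n_df >= 2L) { k <- k + 1L; df2 <- as.numeric(g[k]) }
      if (isTRUE(fam$has_n)) {
        k <- k + 1L
        if (!is.na(g[k])) rep_n <- as.integer(g[k])
      }
      scmp <- .map_cmp(g[k + 1L])
      sval_chr <- g[k + 2L]
      pcmp_chr <- g[k + 3L]
      pval_chr <- g[k + 4L]
      ns_chr <- g[k + 5L]

      sval <- as.numeric(sval_chr)
      skip <- NULL
      if (fam$n_df >= 1L && !(df1 > 0)) skip <- "degrees of freedom not > 0"
      if (fam$n_df >= 2L && !(df2 > 0)) skip <- "degrees of freedom not > 0"
      if (is.null(skip) && fam$type %in% .upper_tail_families && sval < 0)
        skip <- "negative statistic for an upper-tail test family"
      if (is.null(skip) && fam$type == "R" && abs(sval) > 1)
        skip <- "correlation outside [-1, 1]"
      if (!is.na(ns_chr)) {
        pcmp <- "NS"; pval <- NA_real_; pdec <- NA_integer_
      } else {
        pcmp <- .map_cmp(pcmp_chr)
        pval <- as.numeric(pval_chr)
        pdec <- .decimals_of(pval_chr)
        if (is.null(skip) && (pval < 0 || pval > 1))
          skip <- "reported p outside [0, 1]"
      }
      if (!is.null(skip)) {
        message("statconsist: skipping '", fm$raw[i], "' in ",
                doc$source_id, ": ", skip)
        next
      }
      cand[[length(cand) + 1L]] <- data.frame(
        source_id = doc$source_id, raw_text = fm$raw[i],
        test_type = fam$type, df1 = df1, df2 = df2, reported_n = rep_n,
        stat_comparator = scmp, stat_value = sval,
        stat_decimals = .decimals_of(sval_chr),
        p_comparator = pcmp, p_value = pval, p_decimals = pdec,
        one_tailed_context = one_tailed,
        offset = fm$start[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(.empty_records())
  recs <- do.call(rbind, cand)
  recs$len <- nchar(recs$raw_text)
  recs <- recs[order(recs$offset, -recs$len), , drop = FALSE]
  # keep non-overlapping spans, first (leftmost, then longest) wins
  keep <- logical(nrow(recs))
  last_end <- 0L
  for (i in seq_len(nrow(recs))) {
    if (recs$offset[i] > last_end) {
      keep[i] <- TRUE
      last_end <- recs$offset[i] + recs$len[i] - 1L
    }
  }
  recs <- recs[keep, setdiff(names(recs), "len"), drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Detect one-tailed-test language in a document
#'
#' Searches the whole document, case-insensitively, for the keywords
#' "one-tailed", "one-sided" (hyphen or space separated) or "directional".
#' The flag is document-global: it is copied onto every statistic extracted
#' from the document and later lets the consistency check rescue a result
#' whose reported p matches the one-tailed recomputation.
#'
#' @param text a [document_text] or character scalar.
#' @return logical scalar.
#' @export
detect_one_tailed_language <- function(text) {
  doc <- as_document_text(text)
  grepl("(?i)one[\\s-]?(tailed|sided)|directional", doc$text, perl = TRUE)
}
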