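# Synthetic corpus with constructively known ground truth.
#
# Each generated case starts from an unrounded "true" statistic. For a
# consistent case the reported p is the correctly rounded true p (or a
# correct "<" bound), so the reported and recomputed rounding intervals
# both contain the true p and must overlap. For a planted inconsistency
# the reported p is moved to a rounding interval provably disjoint from
# the interval of p-values attainable from the printed statistic — on the
# same side of alpha for a plain inconsistency, on the opposite side for a
# gross one. The labels therefore follow from the construction alone;
# the checker under test plays no part in labelling.

#' Specification of a synthetic corpus
#'
#' @param n_documents number of documents to generate.
#' @param statistics_per_document APA results embedded per document.
#' @param inconsistency_rate total probability that a statistic is planted
#'   inconsistent (gross cases included). Default 0.3.
#' @param gross_rate probability that a statistic is planted as a gross
#'   inconsistency; must not exceed `inconsistency_rate`. Default 0.1.
#' @param alpha significance level the labels are planted against.
#' @param seed integer seed; the corpus is fully reproducible from it.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_documents = 500, statistics_per_document = 4,
                        inconsistency_rate = 0.3, gross_rate = 0.1,
                        alpha = 0.05, seed = 1L) {
  stopifnot(n_documents >= 1, statistics_per_document >= 0,
            inconsistency_rate >= 0, inconsistency_rate <= 1,
            gross_rate >= 0, gross_rate <= inconsistency_rate,
            alpha > 0, alpha < 1)
  structure(list(n_documents = as.integer(n_documents),
                 statistics_per_document = as.integer(statistics_per_document),
                 inconsistency_rate = inconsistency_rate,
                 gross_rate = gross_rate, alpha = alpha,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# round half away from zero at d decimals (the convention print formats use)
.round_half_up <- function(x, d) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}

# upper-tail p for the generator, written locally so truth construction
# does not route through the engine's interval machinery
.gen_p <- function(family, df1, df2, x, one_tailed = FALSE) {
  ax <- abs(x)
  p <- switch(family,
              T = 2 * stats::pt(ax, df1, lower.tail = FALSE),
              Z = 2 * stats::pnorm(ax, lower.tail = FALSE),
              R = {
                if (ax >= 1) 0
                else 2 * stats::pt(ax * sqrt(df1 / (1 - ax^2)), df1,
                                   lower.tail = FALSE)
              },
              F = stats::pf(x, df1, df2, lower.tail = FALSE),
              stats::pchisq(x, df1, lower.tail = FALSE))
  if (one_tailed && family %in% c("T", "Z", "R")) p <- p / 2
  min(max(p, 0), 1)
}

.gen_draw_dfs <- function(family) {
  switch(family,
         T = list(df1 = if (stats::runif(1) < 0.1)
                    round(stats::runif(1, 10, 100), 1)
                  else sample(5:200, 1), df2 = NA_real_),
         F = list(df1 = sample(1:8, 1), df2 = sample(10:120, 1)),
         CHI2 = list(df1 = sample(1:20, 1), df2 = NA_real_),
         Z = list(df1 = NA_real_, df2 = NA_real_),
         R = list(df1 = sample(10:150, 1), df2 = NA_real_),
         list(df1 = sample(1:30, 1), df2 = NA_real_))  # Q family
}

.gen_stat_from_p <- function(family, df1, df2, p) {
  switch(family,
         T = stats::qt(1 - p / 2, df1),
         Z = stats::qnorm(1 - p / 2),
         R = {
           tq <- stats::qt(1 - p / 2, df1)
           tq / sqrt(df1 + tq^2)
         },
         F = stats::qf(1 - p, df1, df2),
         stats::qchisq(1 - p, df1))
}

.fmt_num <- function(x, d) formatC(x, format = "f", digits = d)
.fmt_p_chr <- function(x, d) sub("^(-?)0\\.", "\\1.", .fmt_num(x, d))

#' Generate one synthetic APA result with a known truth label
#'
#' Draws a test family, degrees of freedom and an unrounded true statistic
#' (seeded via the caller's RNG state), prints the statistic at two
#' decimals, and prints a p clause that makes the case consistent, plainly
#' inconsistent, or grossly inconsistent by construction. Cases whose
#' geometry makes the requested label impossible (computed interval
#' straddling alpha) are re-drawn, with bounded retries.
#'
#' @param spec a [corpus_spec()] (supplies `alpha` and rates).
#' @param label force a truth label (`"CONSISTENT"`, `"INCONSISTENCY"`,
#'   `"GROSS"`); `NULL` draws one from the spec's rates.
#' @param one_tailed will the surrounding document carry one-tailed
#'   language? Constrains planted inconsistencies so the one-tailed rescue
#'   cannot silently flip their label.
#' @return list describing the case, including `apa` (the rendered result
#'   string) and `truth_label`.
#' @export
generate_case <- function(spec, label = NULL, one_tailed = FALSE) {
  alpha <- spec$alpha
  if (is.null(label)) {
    u <- stats::runif(1)
    label <- if (u < spec$gross_rate) "GROSS"
             else if (u < spec$inconsistency_rate) "INCONSISTENCY"
             else "CONSISTENT"
  }
  label <- match.arg(label, c("CONSISTENT", "INCONSISTENCY", "GROSS"))
  h3 <- 0.0005   # half-width of a 3-decimal rounding interval
  margin <- 0.001

  for (attempt in 1:100) {
    family <- sample(c("T", "F", "CHI2", "Z", "R", "Q", "QW", "QB"), 1)
    dfs <- .gen_draw_dfs(family)
    repeat {
      true_p <- stats::runif(1, 0.002, 0.98)
      if (abs(true_p - alpha) > 0.002) break
    }
    true_stat <- .gen_stat_from_p(family, dfs$df1, dfs$df2, true_p)
    if (family %in% c("T", "Z", "R") && stats::runif(1) < 0.3)
      true_stat <- -true_stat

    printed_stat <- .round_half_up(true_stat, 2)
    s_lo <- max(abs(printed_stat) - 0.005, 0)
    s_hi <- abs(printed_stat) + 0.005
    if (family == "R") s_hi <- min(s_hi, 1)
    # attainable p interval from the printed statistic (two-tailed)
    plo <- .gen_p(family, dfs$df1, dfs$df2, s_hi)
    phi <- .gen_p(family, dfs$df1, dfs$df2, s_lo)
    sym <- family %in% c("T", "Z", "R")
    one_guard <- one_tailed && sym  # rescue rule could apply

    case <- list(test_type = family, df1 = dfs$df1, df2 = dfs$df2,
                 reported_n = NA_integer_, true_stat = true_stat,
                 true_p = true_p, stat_value = printed_stat,
                 stat_decimals = 2L, truth_label = label,
                 one_tailed = one_tailed)

    if (label == "CONSISTENT") {
      # report the true p (or its one-tailed half when exercising the
      # rescue rule), correctly rounded -- both intervals contain it
      p_report <- true_p
      if (one_guard && stats::runif(1) < 0.7) p_report <- true_p / 2
      if (stats::runif(1) < 0.25) {
        bounds <- c(0.05, 0.01, 0.001)
        ok <- bounds[p_report < bounds - 1e-6]
        if (length(ok)) {
          b <- sample(rep(ok, 2), 1)
          case$p_comparator <- "LT"
          case$p_value <- b
          case$p_decimals <- .decimals_of(.fmt_p_chr(b, if (b < 0.01) 3 else 2))
          return(.finish_case(case))
        }
      }
      p_dec <- sample(2:3, 1)
      if (.round_half_up(p_report, p_dec) == 0) p_dec <- 3L
      case$p_comparator <- "EQ"
      case$p_value <- .round_half_up(p_report, p_dec)
      case$p_decimals <- as.integer(p_dec)
      return(.finish_case(case))
    }

    # planted inconsistencies need the computed interval cleanly on one
    # side of alpha
    side <- if (phi <= alpha - margin) "sig"
            else if (plo >= alpha + margin) "nonsig" else NA
    if (is.na(side)) next

    disjoint <- function(v)
      v + h3 <= plo | v - h3 > phi
    disjoint_one <- function(v) {
      if (!one_guard) return(rep(TRUE, length(v)))
      v + h3 <= plo / 2 | v - h3 > phi / 2
    }

    if (label == "INCONSISTENCY") {
      cands <- if (side == "sig")
        seq(0.001, alpha - 0.001, by = 0.001)
      else
        seq(round(alpha + 0.002, 3), 0.998, by = 0.001)
      ok <- if (side == "sig")
        cands[cands + h3 <= alpha & disjoint(cands) & disjoint_one(cands)]
      else
        cands[cands - h3 > alpha & disjoint(cands) & disjoint_one(cands)]
      if (!length(ok)) next
      case$p_comparator <- "EQ"
      case$p_value <- sample(rep(ok, 2), 1)
      case$p_decimals <- 3L
      return(.finish_case(case))
    }

    # GROSS: reported significance on the opposite side of alpha
    if (side == "sig") {
      # computed clearly significant; report nonsignificant
      if (stats::runif(1) < 0.3) {
        case$p_comparator <- "GT"
        case$p_value <- alpha
        case$p_decimals <- 2L
        return(.finish_case(case))
      }
      cands <- seq(round(alpha + 0.002, 3), 0.998, by = 0.001)
      ok <- cands[cands - h3 > alpha & disjoint(cands) & disjoint_one(cands)]
      if (!length(ok)) next
      case$p_comparator <- "EQ"
      case$p_value <- sample(rep(ok, 2), 1)
      case$p_decimals <- 3L
      return(.finish_case(case))
    } else {
      # computed clearly nonsignificant; report significant, but never in
      # a way the one-tailed rescue could legitimise
      lt_safe <- !one_guard || plo / 2 >= alpha
      if (lt_safe && stats::runif(1) < 0.4) {
        case$p_comparator <- "LT"
        case$p_value <- alpha
        case$p_decimals <- 2L
        return(.finish_case(case))
      }
      cands <- seq(0.001, alpha - 0.001, by = 0.001)
      ok <- cands[cands + h3 <= alpha & disjoint(cands) & disjoint_one(cands)]
      if (!length(ok)) next
      case$p_comparator <- "EQ"
      case$p_value <- sample(rep(ok, 2), 1)
      case$p_decimals <- 3L
      return(.finish_case(case))
    }
  }
  stop("could not construct a '", label, "' case in 100 attempts",
       call. = FALSE)
}

# attach display strings and the rendered APA result
.finish_case <- function(case) {
  if (case$test_type == "CHI2" && stats::runif(1) < 0.5)
    case$reported_n <- case$df1 + sample(50:500, 1)
  case$printed_stat <- if (case$test_type == "R")
    .fmt_p_chr(case$stat_value, case$stat_decimals)
  else
    .fmt_num(case$stat_value, case$stat_decimals)
  case$printed_p <- if (case$p_comparator == "NS") "ns"
    else .fmt_p_chr(case$p_value, case$p_decimals)
  case$apa <- apa_string(case)
  case
}

.df_chr <- function(df) {
  if (df == round(df)) sprintf("%d", as.integer(df))
  else .fmt_num(df, 1)
}

#' Render a synthetic case as an APA result string
#'
#' @param case a case from [generate_case()].
#' @return character scalar such as `"t(28) = 2.14, p = .04"`.
#' @export
apa_string <- function(case) {
  psym <- c(EQ = "=", LT = "<", GT = ">")[[case$p_comparator]]
  pclause <- sprintf("p %s %s", psym, case$printed_p)
  head <- switch(
    case$test_type,
    T = sprintf("t(%s) = %s", .df_chr(case$df1), case$printed_stat),
    R = sprintf("r(%s) = %s", .df_chr(case$df1), case$printed_stat),
    F = sprintf("F(%s, %s) = %s", .df_chr(case$df1), .df_chr(case$df2),
                case$printed_stat),
    Z = sprintf("%s = %s", sample(c("Z", "z"), 1), case$printed_stat),
    CHI2 = if (!is.na(case$reported_n))
      sprintf("\u03c72(%s, N = %d) = %s", .df_chr(case$df1),
              case$reported_n, case$printed_stat)
    else
      sprintf("\u03c72(%s) = %s", .df_chr(case$df1), case$printed_stat),
    Q = sprintf("Q(%s) = %s", .df_chr(case$df1), case$printed_stat),
    QW = sprintf("%s(%s) = %s", sample(c("Qw", "Q_w"), 1),
                 .df_chr(case$df1), case$printed_stat),
    QB = sprintf("%s(%s) = %s", sample(c("Qb", "Q_b"), 1),
                 .df_chr(case$df1), case$printed_stat))
  paste0(head, ", ", pclause)
}

.filler_pool <- c(
  "Participants completed all sessions in randomized order.",
  "Descriptive statistics are reported in the supplementary material.",
  "Data were screened for outliers prior to analysis.",
  "The intervention group received eight weekly sessions.",
  "Baseline characteristics did not differ between groups.",
  "Missing observations were handled by listwise deletion.",
  "Effect sizes were pooled under a random-effects model.",
  "Study quality was assessed independently by two raters.",
  "All analyses were preregistered before data collection.",
  "Follow-up measurements were collected after six months.")

.stat_templates <- c(
  "The main effect was reliable, %s.",
  "The difference between conditions reached significance, %s.",
  "The heterogeneity analysis yielded %s.",
  "The moderator analysis indicated %s.",
  "The association was in the expected direction, %s.",
  "Overall, the pooled test gave %s.")

.one_tailed_sentences <- c(
  "All hypothesis tests were one-tailed given the directional predictions.",
  "A one-sided test was used because the direction was specified a priori.",
  "We formulated a directional hypothesis for the primary outcome.")

.html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# decorate an escaped APA string with the inline markup real articles use
.html_apa <- function(apa) {
  s <- .html_escape(apa)
  s <- sub("^(t|r|F|Z|z|Qw|Q_w|Qb|Q_b|Q)\\(", "<i>\\1</i>(", s)
  s <- sub("^(Z|z) =", "<i>\\1</i> =", s)
  s <- sub("\u03c72", "\u03c7<sup>2</sup>", s, fixed = TRUE)
  sub(", p ", ", <i>p</i> ", s, fixed = TRUE)
}

#' Render synthetic cases as a prose document
#'
#' Embeds each case's APA string in a results-style sentence surrounded by
#' filler prose; inserts a one-tailed keyword sentence when any case is
#' marked one-tailed. The `"html"` format wraps sentences in paragraph tags
#' and italicizes statistic symbols the way journal HTML does.
#'
#' @param cases list of cases from [generate_case()]; may be empty.
#' @param format `"txt"` or `"html"`.
#' @return character scalar: the document source.
#' @export
render_document <- function(cases, format = c("txt", "html")) {
  format <- match.arg(format)
  html <- format == "html"
  sentences <- sample(.filler_pool, 2)
  if (length(cases) && any(vapply(cases, `[[`, logical(1), "one_tailed")))
    sentences <- c(sentences, sample(.one_tailed_sentences, 1))
  for (case in cases) {
    template <- sample(.stat_templates, 1)
    apa <- if (html) .html_apa(case$apa) else case$apa
    filler <- if (html) .html_escape(sample(.filler_pool, 1))
              else sample(.filler_pool, 1)
    sentences <- c(sentences,
                   sprintf(if (html) .html_escape(template) else template,
                           apa),
                   filler)
  }
  if (html) {
    paste0("<html><head><title>Synthetic review</title></head><body>\n",
           paste0("<p>", sentences, "</p>", collapse = "\n"),
           "\n</body></html>\n")
  } else {
    paste(sentences, collapse = " ")
  }
}

#' Generate a full synthetic corpus
#'
#' Seeds the RNG from the spec and generates documents with planted
#' statistics whose consistency labels are known by construction. Roughly
#' 15% of documents carry one-tailed language; planted inconsistencies in
#' those documents are constrained so the one-tailed rescue rule cannot
#' change their label.
#'
#' @param spec a [corpus_spec()].
#' @return list with elements `spec`, `documents` (each with `id`, `cases`,
#'   `txt`, `html`) and `truth`, a data.frame with one row per planted
#'   statistic (`doc`, `index`, `test_type`, `truth_label`, `one_tailed`,
#'   `apa`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  docs <- vector("list", spec$n_documents)
  truth <- vector("list", spec$n_documents)
  for (d in seq_len(spec$n_documents)) {
    one_tailed <- stats::runif(1) < 0.15
    cases <- lapply(seq_len(spec$statistics_per_document), function(i)
      generate_case(spec, one_tailed = one_tailed))
    id <- sprintf("doc_%04d", d)
    docs[[d]] <- list(id = id, cases = cases,
                      txt = render_document(cases, "txt"),
                      html = render_document(cases, "html"))
    truth[[d]] <- data.frame(
      doc = id,
      index = seq_along(cases),
      test_type = vapply(cases, `[[`, character(1), "test_type"),
      truth_label = vapply(cases, `[[`, character(1), "truth_label"),
      one_tailed = vapply(cases, `[[`, logical(1), "one_tailed"),
      apa = vapply(cases, `[[`, character(1), "apa"),
      stringsAsFactors = FALSE)
  }
  list(spec = spec, documents = docs, truth = do.call(rbind, truth))
}

#' Write a synthetic corpus to disk
#'
#' Emits one file per document in the requested formats plus a
#' `truth.csv` ground-truth table.
#'
#' @param corpus output of [generate_corpus()].
#' @param dir target directory (created if needed).
#' @param formats subset of `c("txt", "html")`.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, formats = c("txt", "html")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    if ("txt" %in% formats)
      writeLines(doc$txt, file.path(dir, paste0(doc$id, ".txt")),
                 useBytes = TRUE)
    if ("html" %in% formats)
      writeLines(doc$html, file.path(dir, paste0(doc$id, ".html")),
                 useBytes = TRUE)
  }
  utils::write.csv(corpus$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Score flagged verdicts against planted ground truth
#'
#' @param flagged logical vector: was each statistic flagged inconsistent
#'   (the report's `error` column)?
#' @param truth character vector of planted labels (`"CONSISTENT"`,
#'   `"INCONSISTENCY"`, `"GROSS"`), or a logical vector of true
#'   inconsistency indicators, aligned one-to-one with `flagged`.
#' @return list with `sensitivity` (true-positive rate among planted
#'   inconsistencies), `specificity` (true-negative rate among planted
#'   consistent results) and `accuracy`.
#' @export
evaluate_detection <- function(flagged, truth) {
  if (is.character(truth) || is.factor(truth))
    truth <- as.character(truth) != "CONSISTENT"
  stopifnot(is.logical(flagged), is.logical(truth))
  if (length(flagged) != length(truth))
    stop("flagged and truth must have equal length", call. = FALSE)
  list(sensitivity = mean(flagged[truth]),
       specificity = mean(!flagged[!truth]),
       accuracy = mean(flagged == truth))
}
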