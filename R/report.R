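#' Check documents or a text snippet for reporting inconsistencies
#'
#' Orchestrates the full pipeline: ingest each input (literal text, file, or
#' directory), extract APA-style NHST results, recompute p-values, and
#' classify each result. Mirrors the conventional output schema: `raw` is
#' the extracted statistic, `computed` the recomputed p-value, `error`
#' whether the result is inconsistent, and `decision_error` whether the
#' inconsistency is gross (the significance conclusion changes).
#'
#' @param inputs character vector of file paths, directory paths, and/or
#'   literal text snippets (anything that does not name an existing file or
#'   directory is treated as literal text).
#' @param config a [consist_config()].
#' @return data.frame with one row per extracted statistic, in document
#'   order within lexicographic file order: `source`, `raw`, `test_type`,
#'   `df1`, `df2`, `reported_p`, `computed`, `error`, `decision_error`,
#'   `one_tailed_applied`.
#' @examples
#' run_check("Qb(1) = 3.78, p < .05")     # 1 row, gross inconsistency
#' run_check("t(28) = 2.14, p = .04")     # 1 row, consistent
#' @export
run_check <- function(inputs, config = consist_config()) {
  stopifnot(is.character(inputs), length(inputs) >= 1L)
  docs <- list()
  for (x in inputs) {
    if (dir.exists(x)) {
      docs <- c(docs, scan_directory(x, recursive = config$recursive))
    } else if (file.exists(x)) {
      ext <- tolower(tools::file_ext(x))
      docs <- c(docs, list(switch(ext,
                                  html = , htm = html_to_text(x),
                                  pdf = pdf_to_text(x),
                                  load_text(x))))
    } else {
      docs <- c(docs, list(load_text(x)))
    }
  }
  rows <- lapply(docs, function(doc) {
    recs <- find_statistics(doc)
    if (!nrow(recs)) return(NULL)
    result_rows(check_records(recs, config))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    message("statconsist: no APA-style statistics detected")
    return(.empty_result_rows())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_result_rows <- function() {
  data.frame(source = character(), raw = character(),
             test_type = character(), df1 = numeric(), df2 = numeric(),
             reported_p = character(), computed = numeric(),
             error = logical(), decision_error = logical(),
             one_tailed_applied = logical(), stringsAsFactors = FALSE)
}

# display string for the reported p clause, APA-style (no leading zero)
.reported_p_display <- function(p_comparator, p_value, p_decimals) {
  if (p_comparator == "NS") return("ns")
  sym <- c(EQ = "=", LT = "<", GT = ">")[[p_comparator]]
  val <- formatC(p_value, format = "f", digits = p_decimals)
  paste(sym, sub("^0\\.", ".", val))
}

#' Convert checked records to the tabular report schema
#'
#' @param checked output of [check_records()].
#' @return data.frame in the [run_check()] column layout.
#' @export
result_rows <- function(checked) {
  if (!nrow(checked)) return(.empty_result_rows())
  data.frame(
    source = checked$source_id,
    raw = checked$raw_text,
    test_type = checked$test_type,
    df1 = checked$df1,
    df2 = checked$df2,
    reported_p = vapply(seq_len(nrow(checked)), function(i)
      .reported_p_display(checked$p_comparator[i], checked$p_value[i],
                          checked$p_decimals[i]), character(1)),
    computed = checked$computed_p,
    error = !checked$consistent,
    decision_error = checked$gross,
    one_tailed_applied = checked$one_tailed_applied,
    stringsAsFactors = FALSE)
}

#' Write a result table as RFC 4180 CSV
#'
#' Header row carries the result column names; booleans are written as the
#' literals `TRUE`/`FALSE`; the recomputed p is printed with six
#' significant digits; text fields (including raw spans containing commas)
#' are quoted. Values round-trip through [utils::read.csv()].
#'
#' @param rows data.frame from [run_check()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  out <- rows
  out$computed <- formatC(rows$computed, digits = 6, format = "g")
  for (col in c("error", "decision_error", "one_tailed_applied"))
    out[[col]] <- ifelse(rows[[col]], "TRUE", "FALSE")
  con <- tryCatch(suppressWarnings(file(path, "w", encoding = "UTF-8")),
                  error = function(e)
                    stop("cannot write to ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = which(
    vapply(out, is.character, logical(1))), na = "NA")
  invisible(path)
}

#' Read back a result CSV written by [write_results_csv()]
#'
#' @param path CSV path.
#' @return data.frame in the [run_check()] column layout.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(source = "character",
                                       raw = "character",
                                       test_type = "character",
                                       reported_p = "character"))
  for (col in c("error", "decision_error", "one_tailed_applied"))
    df[[col]] <- as.logical(df[[col]])
  df$computed <- as.numeric(df$computed)
  df
}
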