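#' Normalized document text
#'
#' Container for the plain text of one source document after unicode and
#' whitespace normalization, together with its provenance. All extraction
#' functions in the package operate on this representation.
#'
#' @param text character scalar, the normalized text.
#' @param source_id identifier for the document (file name, or `"text-input"`
#'   for literal strings).
#' @param format one of `"TXT"`, `"HTML"`, `"PDF"`.
#' @param warnings character vector of conversion warnings accumulated while
#'   producing the text.
#' @return An object of class `document_text`: a list with elements
#'   `source_id`, `format`, `text` and `conversion_warnings`.
#' @export
document_text <- function(text, source_id = "text-input", format = "TXT",
                          warnings = character()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  format <- match.arg(format, c("TXT", "HTML", "PDF"))
  structure(
    list(source_id = as.character(source_id), format = format,
         text = text, conversion_warnings = as.character(warnings)),
    class = "document_text"
  )
}

#' @export
print.document_text <- function(x, ...) {
  cat(sprintf("<document_text> %s [%s], %d chars", x$source_id, x$format,
              nchar(x$text)))
  if (length(x$conversion_warnings))
    cat(sprintf(", %d warning(s)", length(x$conversion_warnings)))
  cat("\n")
  invisible(x)
}

# Characters that survive PDF/HTML conversion as near-look-alikes of ASCII
# and silently break the pattern grammar. NFKC handles superscripts,
# ligatures and italic math letters; the rest are mapped explicitly.
.char_map <- c(
  "\u2212" = "-",  # minus sign
  "\u2013" = "-",  # en dash
  "\u2014" = "-",  # em dash
  "\u2010" = "-",  # hyphen
  "\u2011" = "-",  # non-breaking hyphen
  "\u00a0" = " ",  # no-break space
  "\u2018" = "'", "\u2019" = "'",
  "\u201c" = "\"", "\u201d" = "\""
)

#' Normalize text for statistic extraction
#'
#' Applies unicode NFKC normalization (which flattens superscripts, ligatures
#' and mathematical-alphanumeric letters to their ASCII counterparts), maps
#' dash/space look-alikes to plain ASCII, strips control characters other
#' than newline, and collapses runs of horizontal whitespace to single
#' spaces. Idempotent: normalizing normalized text is the identity.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  for (from in names(.char_map))
    x <- gsub(from, .char_map[[from]], x, fixed = TRUE)
  x <- gsub("\r\n?", "\n", x)
  x <- gsub("\t", " ", x, fixed = TRUE)
  # drop remaining control/format characters, keep newline
  x <- gsub("(?![\n])[\\p{Cc}\\p{Cf}]", "", x, perl = TRUE)
  x <- gsub(" {2,}", " ", x)
  x <- gsub(" ?\n ?", "\n", x)
  x
}

#' Load a literal string or a plain-text file
#'
#' @param x a literal character string containing text to check, or the path
#'   to a readable `.txt` file. A value that names an existing file is read
#'   from disk; anything else is treated as literal text.
#' @return a [document_text] with format `"TXT"`.
#' @export
load_text <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x) && !dir.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
    document_text(normalize_text(txt), source_id = basename(x))
  } else {
    document_text(normalize_text(x), source_id = "text-input")
  }
}

# Depth-first text extraction: block-level elements contribute newlines so
# that text in adjacent paragraphs or table cells cannot fuse into one token.
.block_tags <- c("p", "div", "li", "tr", "td", "th", "table", "ul", "ol",
                 "h1", "h2", "h3", "h4", "h5", "h6", "section", "article",
                 "blockquote", "figcaption", "caption")

.html_node_text <- function(node, out) {
  type <- xml2::xml_type(node)
  if (type == "text") {
    out$push(xml2::xml_text(node))
    return(invisible())
  }
  if (type != "element") return(invisible())
  name <- xml2::xml_name(node)
  if (name %in% c("script", "style")) return(invisible())
  if (name == "br") { out$push("\n"); return(invisible()) }
  block <- name %in% .block_tags
  if (block) out$push("\n")
  for (child in xml2::xml_contents(node)) .html_node_text(child, out)
  if (block) out$push("\n")
  invisible()
}

#' Convert an HTML article to normalized plain text
#'
#' Scripts and styles are dropped; block-level elements become line breaks;
#' inline markup is flattened so that `<i>t</i>(28)` yields `t(28)` and
#' `&chi;<sup>2</sup>` yields `χ2`.
#'
#' @param x path to an `.html`/`.htm` file, or a character scalar of HTML
#'   markup.
#' @return a [document_text] with format `"HTML"`.
#' @export
html_to_text <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  src <- if (file.exists(x) && !dir.exists(x)) basename(x) else "html-input"
  doc <- tryCatch(xml2::read_html(x, encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot parse HTML input '", src, "': ",
                         conditionMessage(e), call. = FALSE))
  warns <- character()
  root <- xml2::xml_root(doc)
  buf <- new.env()
  buf$parts <- character()
  buf$push <- function(s) buf$parts <- c(buf$parts, s)
  .html_node_text(root, buf)
  txt <- paste(buf$parts, collapse = "")
  txt <- normalize_text(txt)
  txt <- gsub("\n{2,}", "\n", txt)
  txt <- sub("^\n+", "", sub("\n+$", "", txt))
  document_text(txt, source_id = src, format = "HTML", warnings = warns)
}

#' Convert all articles in a directory to normalized plain text
#'
#' Processes every `*.txt`, `*.html`, `*.htm` and `*.pdf` file in
#' lexicographic name order. A file that fails to convert is logged via
#' [message()] and skipped; the batch continues.
#'
#' @param dir_path readable directory.
#' @param recursive descend into subdirectories? Default `FALSE`.
#' @return list of [document_text] objects, possibly empty.
#' @export
scan_directory <- function(dir_path, recursive = FALSE) {
  if (!dir.exists(dir_path))
    stop("not a directory: ", dir_path, call. = FALSE)
  files <- list.files(dir_path, pattern = "\\.(txt|html|htm|pdf)$",
                      ignore.case = TRUE, recursive = recursive,
                      full.names = TRUE)
  files <- files[order(files)]
  out <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    res <- tryCatch(
      switch(ext,
             txt = load_text(f),
             html = , htm = html_to_text(f),
             pdf = pdf_to_text(f)),
      error = function(e) {
        message("statconsist: skipping '", basename(f), "': ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  out
}

# Coerce character input to document_text where convenient.
as_document_text <- function(x) {
  if (inherits(x, "document_text")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(document_text(normalize_text(x)))
  stop("expected a document_text or a character scalar", call. = FALSE)
}
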