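# Minimal reader and writer for text-based PDF files.
#
# The reader targets the subset of PDF that carries article body text:
# literal strings shown with Tj / ' / TJ inside content streams, stored
# either uncompressed or FlateDecode-compressed (zlib). It does not handle
# hex strings, CID-encoded fonts, or scanned pages — those produce a
# conversion warning or error rather than silent garbage. The writer emits
# single-page uncompressed (or Flate) PDFs used to build test fixtures in
# code, so the reader/writer pair round-trips by construction.

# positions (1-based) of a literal byte pattern in a raw vector, via a
# NUL-safe character shadow of the bytes
.raw_positions <- function(chr, pattern) {
  m <- gregexpr(pattern, chr, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# ASCII shadow of raw bytes: anything outside printable ASCII (plus
# newline/carriage return) becomes a space, so character positions equal
# byte positions and no encoding translation can fail. Extracted text is
# therefore ASCII-only; the writer transliterates accordingly.
.ascii_shadow <- function(bytes) {
  keep <- (bytes >= as.raw(0x20) & bytes <= as.raw(0x7e)) |
    bytes == as.raw(0x0a) | bytes == as.raw(0x0d)
  bytes[!keep] <- as.raw(0x20)
  rawToChar(bytes)
}

.pdf_unescape <- function(s) {
  out <- character()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "\\" && i < n) {
      nxt <- substr(s, i + 1L, i + 1L)
      if (nxt %in% c("(", ")", "\\")) { out <- c(out, nxt); i <- i + 2L }
      else if (nxt == "n") { out <- c(out, "\n"); i <- i + 2L }
      else if (nxt == "r") { out <- c(out, "\r"); i <- i + 2L }
      else if (nxt == "t") { out <- c(out, "\t"); i <- i + 2L }
      else if (grepl("[0-7]", nxt)) {
        oct <- regmatches(s, regexpr("^[0-7]{1,3}",
                                     substr(s, i + 1L, n)))[[1]]
        out <- c(out, rawToChar(as.raw(strtoi(oct, base = 8L))))
        i <- i + 1L + nchar(oct)
      } else { out <- c(out, nxt); i <- i + 2L }
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# Extract shown text from one decoded content stream. Literal strings are
# concatenated in order; Td/TD/T* positioning operators become newlines.
.content_stream_text <- function(stream_chr) {
  pat <- "\\((?:[^()\\\\]|\\\\.)*\\)|T[dD]|T\\*|'"
  m <- gregexpr(pat, stream_chr, perl = TRUE)[[1]]
  if (m[1] == -1L) return("")
  toks <- regmatches(stream_chr, list(m))[[1]]
  parts <- character()
  for (tok in toks) {
    if (startsWith(tok, "(")) {
      parts <- c(parts, .pdf_unescape(substr(tok, 2L, nchar(tok) - 1L)))
    } else {
      parts <- c(parts, "\n")
    }
  }
  paste(parts, collapse = "")
}

#' Convert a text-based PDF article to normalized plain text
#'
#' Extracts the text shown by content streams (uncompressed or
#' FlateDecode), expands ligatures, rejoins words hyphenated across line
#' breaks, and normalizes dash variants. Encrypted or image-only PDFs raise
#' a conversion error; streams that fail to decompress are recorded in the
#' warning list.
#'
#' @param path path to a `.pdf` file.
#' @return a [document_text] with format `"PDF"`.
#' @export
pdf_to_text <- function(path) {
  if (!file.exists(path)) stop("cannot read PDF: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) == 0L) stop("empty PDF file: ", path, call. = FALSE)
  chr <- .ascii_shadow(bytes)
  if (!grepl("%PDF", chr, fixed = TRUE))
    stop("not a PDF file: ", path, call. = FALSE)
  if (grepl("/Encrypt", chr, fixed = TRUE))
    stop("encrypted PDF not supported: ", path, call. = FALSE)

  starts <- .raw_positions(chr, "stream")
  ends <- .raw_positions(chr, "endstream")
  starts <- setdiff(starts, ends + 3L)  # "stream" inside "endstream"
  warns <- character()
  pieces <- character()
  for (s in starts) {
    e <- ends[ends > s]
    if (!length(e)) next
    e <- min(e)
    # data begins after "stream" + EOL
    d0 <- s + 6L
    while (d0 <= length(bytes) && bytes[d0] %in% as.raw(c(10L, 13L)))
      d0 <- d0 + 1L
    head <- substr(chr, max(1L, s - 400L), s)
    # trust the dictionary's /Length where present: trailing EOL guessing
    # would truncate compressed data that happens to end in 0x0A/0x0D
    len <- regmatches(head, regexpr("/Length\\s+\\d+", head))
    if (length(len)) {
      d1 <- d0 + as.integer(sub("/Length\\s+", "", len)) - 1L
      if (d1 >= e) d1 <- e - 1L
    } else {
      d1 <- e - 1L
      while (d1 >= d0 && bytes[d1] %in% as.raw(c(10L, 13L)))
        d1 <- d1 - 1L
    }
    if (d1 < d0) next
    data <- bytes[d0:d1]
    if (grepl("/FlateDecode", head, fixed = TRUE)) {
      data <- tryCatch(memDecompress(data, type = "gzip"),
                       error = function(e) NULL)
      if (is.null(data)) {
        warns <- c(warns, sprintf("stream at byte %d: decompression failed", s))
        next
      }
    }
    pieces <- c(pieces, .content_stream_text(.ascii_shadow(data)))
  }
  txt <- paste(pieces[nzchar(pieces)], collapse = "\n")
  if (!nzchar(gsub("\\s", "", txt)))
    stop("no extractable text in PDF (image-only or empty): ", path,
         call. = FALSE)
  # rejoin words hyphenated at line breaks: "signifi-\ncant" -> "significant"
  txt <- gsub("([A-Za-z])-\n([a-z])", "\\1\\2", txt)
  document_text(normalize_text(txt), source_id = basename(path),
                format = "PDF", warnings = warns)
}

.pdf_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("(", "\\(", s, fixed = TRUE)
  s <- gsub(")", "\\)", s, fixed = TRUE)
  s
}

#' Write a minimal single-page PDF containing the given text
#'
#' Renders text line-by-line with a base-14 font, optionally compressing the
#' content stream with Flate. Intended for building PDF fixtures in code;
#' non-ASCII characters are transliterated (the chi-squared symbol becomes
#' `X2`) because the base fonts are not unicode-capable.
#'
#' @param text character scalar or vector of lines.
#' @param path output file path.
#' @param compress compress the content stream? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_minimal_pdf <- function(text, path, compress = FALSE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (!length(lines)) lines <- ""
  lines <- gsub("χ2", "X2", lines, fixed = TRUE)
  lines <- gsub("χ", "X", lines, fixed = TRUE)
  lines <- iconv(lines, "UTF-8", "ASCII", sub = "?")
  # wrap long lines so the page stays plausible
  lines <- unlist(lapply(lines, function(l) {
    if (nchar(l) <= 90L) return(l)
    regmatches(l, gregexpr(".{1,90}( |$)", l))[[1]]
  }))
  body <- paste0("(", .pdf_escape(lines), ") Tj T*", collapse = "\n")
  content <- paste0("BT\n/F1 10 Tf\n12 TL\n50 742 Td\n", body, "\nET\n")
  craw <- charToRaw(content)
  filter <- ""
  if (compress) {
    craw <- memCompress(craw, type = "gzip")
    filter <- " /Filter /FlateDecode"
  }

  objs <- list(
    "<< /Type /Catalog /Pages 2 0 R >>",
    "<< /Type /Pages /Kids [3 0 R] /Count 1 >>",
    paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] ",
           "/Resources << /Font << /F1 4 0 R >> >> /Contents 5 0 R >>"),
    "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  pos <- 0L
  put <- function(x) {
    r <- if (is.raw(x)) x else charToRaw(x)
    writeBin(r, con)
    pos <<- pos + length(r)
    invisible()
  }
  offsets <- integer(5)
  put("%PDF-1.4\n")
  for (i in seq_along(objs)) {
    offsets[i] <- pos
    put(sprintf("%d 0 obj\n%s\nendobj\n", i, objs[[i]]))
  }
  offsets[5] <- pos
  put(sprintf("5 0 obj\n<< /Length %d%s >>\nstream\n", length(craw), filter))
  put(craw)
  put("\nendstream\nendobj\n")
  xref <- pos
  put("xref\n0 6\n0000000000 65535 f \n")
  for (o in offsets) put(sprintf("%010d 00000 n \n", o))
  put(sprintf("trailer\n<< /Size 6 /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
              xref))
  invisible(path)
}
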