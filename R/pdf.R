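# Minimal PDF writer/reader for single-column fixture documents.
#
# The writer emits uncompressed PDF 1.4: one content stream per page, text
# shown line by line with Tj inside a single BT/ET block, Helvetica only.
# The reader understands exactly that subset (plus TJ arrays), which covers
# every file the synthetic-corpus generator produces. It is not a general
# PDF parser: compressed streams, CID fonts and multi-column layouts are
# out of scope, and real journal PDFs should be converted to plain text
# with an external tool before ingestion.

PDF_LINES_PER_PAGE <- 58L
PDF_CHARS_PER_LINE <- 90L

pdf_escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("(", "\\(", x, fixed = TRUE)
  gsub(")", "\\)", x, fixed = TRUE)
}

pdf_unescape_string <- function(x) {
  # reverse of pdf_escape_string; also handles octal escapes defensively
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    s <- gsub("\\\\([0-7]{1,3})", "", s)
    s <- gsub("\\\\n", "\n", s)
    s <- gsub("\\\\([()\\\\])", "\\1", s)
    out[[i]] <- s
  }
  out
}

# hard-wrap one paragraph at word boundaries
pdf_wrap_line <- function(line, width = PDF_CHARS_PER_LINE) {
  if (nchar(line) <= width) return(line)
  words <- strsplit(line, " ", fixed = TRUE)[[1]]
  out <- character(0)
  cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) > width && nzchar(cur)) {
      out <- c(out, cur)
      cur <- w
    } else {
      cur <- cand
    }
  }
  c(out, cur)
}

#' Write plain text as a simple single-column PDF
#'
#' Renders text into an uncompressed PDF (Helvetica, one column, fixed line
#' grid). Used by the synthetic-corpus generator to produce PDF fixtures
#' whose text round-trips through [load_document()].
#'
#' @param text Character scalar; `\n` separates lines, blank lines are kept.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [pdf_extract_text()]
#' @export
pdf_write_text <- function(text, path) {
  stopifnot(is.character(text), length(text) == 1)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  lines <- unlist(lapply(lines, pdf_wrap_line), use.names = FALSE)
  pages <- split(lines, (seq_along(lines) - 1L) %/% PDF_LINES_PER_PAGE)

  streams <- vapply(pages, function(pl) {
    body <- paste0("(", pdf_escape_string(pl), ") Tj T*", collapse = "\n")
    paste0("BT /F1 10 Tf 12 TL 50 780 Td\n", body, "\nET")
  }, character(1))

  n_pages <- length(streams)
  # object layout: 1 catalog, 2 pages, 3 font, then per page: page obj, stream obj
  objs <- character(0)
  kids <- paste(sprintf("%d 0 R", 3L + seq_len(n_pages) * 2L - 1L), collapse = " ")
  objs[1] <- "1 0 obj\n<< /Type /Catalog /Pages 2 0 R >>\nendobj\n"
  objs[2] <- sprintf("2 0 obj\n<< /Type /Pages /Kids [%s] /Count %d >>\nendobj\n",
                     kids, n_pages)
  objs[3] <- "3 0 obj\n<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>\nendobj\n"
  for (i in seq_len(n_pages)) {
    page_id <- 3L + i * 2L - 1L
    stream_id <- page_id + 1L
    objs[page_id] <- sprintf(paste0(
      "%d 0 obj\n<< /Type /Page /Parent 2 0 R /MediaBox [0 0 595 842] ",
      "/Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>\nendobj\n"),
      page_id, stream_id)
    objs[stream_id] <- sprintf(
      "%d 0 obj\n<< /Length %d >>\nstream\n%s\nendstream\nendobj\n",
      stream_id, nchar(streams[[i]], type = "bytes"), streams[[i]])
  }

  header <- "%PDF-1.4\n"
  offsets <- integer(length(objs))
  pos <- nchar(header, type = "bytes")
  for (i in seq_along(objs)) {
    offsets[i] <- pos
    pos <- pos + nchar(objs[[i]], type = "bytes")
  }
  xref <- paste0(
    "xref\n0 ", length(objs) + 1L, "\n0000000000 65535 f \n",
    paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"), "\n")
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
    length(objs) + 1L, pos)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(paste0(
    header, paste(objs, collapse = ""), xref, trailer))), con)
  invisible(path)
}

#' Extract text from a simple uncompressed PDF
#'
#' Companion reader to [pdf_write_text()]: pulls show-text operators (`Tj`,
#' `TJ`) out of uncompressed content streams in page order. Compressed or
#' image-only PDFs yield empty text (and an ingestion error upstream).
#'
#' @param path PDF file path.
#' @return List with `text` (character scalar, lines joined by `\n`) and
#'   `page_count` (integer).
#' @export
pdf_extract_text <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!startsWith(txt, "%PDF")) {
    abort(sprintf("not a PDF file: %s", path), class = "vivomine_ingest_error")
  }
  if (grepl("/Encrypt", txt, fixed = TRUE)) {
    abort(sprintf("encrypted PDF cannot be read: %s", path),
          class = "vivomine_ingest_error")
  }
  streams <- stringr::str_match_all(
    txt, stringr::regex("stream\r?\n(.*?)\r?\nendstream", dotall = TRUE))[[1]][, 2]
  page_lines <- lapply(streams, function(s) {
    shows <- stringr::str_match_all(
      s, "\\(((?:[^()\\\\]|\\\\.)*)\\)\\s*(?:Tj|TJ)")[[1]][, 2]
    pdf_unescape_string(shows)
  })
  page_lines <- page_lines[vapply(page_lines, length, 1L) > 0]
  list(
    text = paste(unlist(page_lines), collapse = "\n"),
    page_count = max(length(page_lines), length(streams))
  )
}
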