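# IMRaD sectioning: heading detection, references stripping, scope
# selection. Headings are recognised only at line starts of normalized
# text, case-insensitively, tolerant of numbering ("2. Methods") and
# trailing punctuation, so body-text mentions of the word "results" or
# "references" never open a section.

SECTION_NAMES <- c("abstract", "introduction", "methods", "results",
                   "discussion", "other")

#' Default heading synonym table
#'
#' Maps journal heading variants onto the canonical IMRaD section names.
#' Extend or replace to adapt to a field's conventions.
#'
#' @return Named list: canonical section name -> character vector of
#'   heading phrases (matched case-insensitively, longest first).
#' @export
default_headings <- function() {
  list(
    abstract = c("abstract", "summary"),
    introduction = c("introduction", "background"),
    methods = c("materials and methods", "material and methods",
                "methods and materials", "experimental procedures",
                "methods"),
    results = c("results and discussion", "results"),
    discussion = c("discussion", "general discussion"),
    references = c("references", "reference list", "bibliography",
                   "literature cited")
  )
}

heading_line_regex <- function(phrases) {
  alts <- paste(phrases[order(-nchar(phrases))], collapse = "|")
  sprintf("^\\s*(?:\\d+(?:\\.\\d+)*\\.?\\s+|[IVXLC]+\\.\\s+)?(?:%s)\\s*[:.]?\\s*$",
          alts)
}

# locate heading lines; returns tibble(section, line, start, end) with
# 0-based half-open character offsets into `text`
find_headings <- function(text, headings = default_headings()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  starts <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  hits <- purrr::imap(headings, function(phrases, section) {
    m <- stringr::str_detect(
      lines, stringr::regex(heading_line_regex(phrases), ignore_case = TRUE))
    tibble(section = section, line = which(m))
  })
  hits <- bind_rows(hits)
  hits$start <- starts[hits$line]
  hits$end <- hits$start + nchar(lines[hits$line])
  arrange(hits, .data$start)
}

#' Strip the references section from text
#'
#' Removes the terminal references block: everything from the references
#' heading ("References", "Bibliography", "Literature Cited", ...) that has
#' no later non-references heading after it, to the end of the text. A
#' "References" entry in a table of contents is followed by other section
#' headings and therefore never triggers stripping; inline uses of the
#' word ("we cite references throughout") are not line-anchored headings
#' and are ignored too.
#'
#' @param text Character scalar (normalized text; see [normalize_text()]).
#' @param headings Heading synonym table, see [default_headings()].
#' @return Text without the references block; unchanged if no references
#'   heading is found. Idempotent.
#' @export
strip_references <- function(text, headings = default_headings()) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) return(text)
  rs <- refs_start_offset(find_headings(text, headings))
  if (is.na(rs)) return(text)
  substr(text, 1L, rs)
}

# 0-based offset where the terminal references block starts, or NA.
# Among references headings with no later non-references heading, the
# earliest wins, so restripping the result is a no-op.
refs_start_offset <- function(h) {
  refs <- h[h$section == "references", , drop = FALSE]
  if (nrow(refs) == 0) return(NA_integer_)
  other <- h$start[h$section != "references"]
  terminal <- vapply(refs$start, function(st) !any(other > st), logical(1))
  if (!any(terminal)) return(NA_integer_)
  min(refs$start[terminal])
}

#' Segment a document into IMRaD sections
#'
#' Each recognized heading opens a section running to the next recognized
#' heading or the end of text. The references block (last references
#' heading onward) is excluded from every section and from
#' `body_minus_references`. Leading text before the first heading is
#' treated as the abstract when no explicit abstract heading exists,
#' otherwise filed under `other`. Text under unrecognized headings accrues
#' to the preceding section.
#'
#' If no heading at all is recognized, the whole text is assigned to
#' `other` and `no_headings` is flagged so downstream scoping can fall
#' back to the full body.
#'
#' @param doc A `raw_document` from [load_document()], or a character
#'   scalar of (cleaned) text.
#' @param headings Heading synonym table ([default_headings()]).
#' @param doc_id Identifier used when `doc` is a bare string.
#' @param normalize Run [normalize_text()] first (default). Disable when
#'   the text has already been normalized: normalization reduces paragraph
#'   breaks to single newlines, so running it twice would merge heading
#'   lines into their following paragraph.
#' @return A `sectioned_document`: list with `doc_id`, `sections` (named
#'   list over abstract / introduction / methods / results / discussion /
#'   other), `body_minus_references`, `heading_spans` (tibble of section,
#'   start, end; 0-based half-open offsets), `no_headings` flag.
#' @export
segment_sections <- function(doc, headings = default_headings(),
                             doc_id = NULL, normalize = TRUE) {
  if (inherits(doc, "raw_document")) {
    text <- if (normalize) normalize_text(doc$raw_text) else doc$raw_text
    doc_id <- doc_id %||% doc$doc_id
  } else {
    stopifnot(is.character(doc), length(doc) == 1)
    text <- if (normalize) normalize_text(doc) else doc
    doc_id <- doc_id %||% "doc"
  }

  h <- find_headings(text, headings)
  rs <- refs_start_offset(h)
  ref_start <- if (is.na(rs)) nchar(text) else rs
  body <- stringr::str_trim(substr(text, 1L, ref_start))
  h <- filter(h, .data$section != "references", .data$start < ref_start)

  sections <- stats::setNames(as.list(rep("", length(SECTION_NAMES))),
                              SECTION_NAMES)
  spans <- tibble(section = character(0), start = integer(0), end = integer(0))

  if (nrow(h) == 0) {
    sections$other <- body
    return(new_sectioned_document(doc_id, sections, body, spans,
                                  no_headings = TRUE))
  }

  # leading text before the first heading
  lead <- stringr::str_trim(substr(text, 1L, h$start[1]))
  if (nzchar(lead)) {
    lead_section <- if (any(h$section == "abstract")) "other" else "abstract"
    sections[[lead_section]] <- lead
    spans <- bind_rows(spans, tibble(section = lead_section, start = 0L,
                                     end = h$start[1]))
  }

  block_end <- c(h$start[-1], ref_start)
  for (i in seq_len(nrow(h))) {
    sec <- h$section[i]
    chunk <- stringr::str_trim(substr(text, h$end[i] + 1L, block_end[i]))
    sections[[sec]] <- if (nzchar(sections[[sec]]))
      paste(sections[[sec]], chunk, sep = "\n") else chunk
    spans <- bind_rows(spans, tibble(section = sec,
                                     start = as.integer(h$start[i]),
                                     end = as.integer(block_end[i])))
  }
  new_sectioned_document(doc_id, sections, body, spans, no_headings = FALSE)
}

new_sectioned_document <- function(doc_id, sections, body, spans, no_headings) {
  structure(
    list(doc_id = doc_id, sections = sections,
         body_minus_references = body,
         heading_spans = spans, no_headings = no_headings),
    class = "sectioned_document"
  )
}

#' @export
print.sectioned_document <- function(x, ...) {
  sizes <- vapply(x$sections, nchar, 1L)
  cat(sprintf("<sectioned_document> %s\n", x$doc_id))
  cat(paste(sprintf("  %s: %d chars", names(sizes), sizes), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Select the text an item is matched against
#'
#' `methods` returns the methods section, falling back to the full body
#' (minus references) when no methods section was found — the fallback is
#' flagged on the result so runs can be stratified by it. `full_minus_refs`
#' returns the body without the references block; `abstract` the abstract
#' section.
#'
#' @param doc A `sectioned_document`.
#' @param scope One of `"methods"`, `"full_minus_refs"`, `"abstract"`.
#' @param allow_fallback Disable to make an empty methods section return
#'   empty text instead of the full body.
#' @return Character scalar; attribute `fallback_used` is `TRUE` when the
#'   methods fallback fired.
#' @export
scope_text <- function(doc, scope = c("methods", "full_minus_refs", "abstract"),
                       allow_fallback = TRUE) {
  stopifnot(inherits(doc, "sectioned_document"))
  scope <- match.arg(scope)
  out <- switch(scope,
    full_minus_refs = doc$body_minus_references,
    abstract = doc$sections$abstract,
    methods = {
      m <- doc$sections$methods
      if (!nzchar(m) && allow_fallback) {
        structure(doc$body_minus_references, fallback_used = TRUE)
      } else m
    })
  if (is.null(attr(out, "fallback_used"))) attr(out, "fallback_used") <- FALSE
  out
}
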