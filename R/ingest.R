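# Ingestion: PDFs or plain-text files -> normalized document text,
# plus the keyword-cleaning pass that suppresses known false-positive
# phrases (e.g. "random primer") before any pattern matching happens.

#' Load one publication into a raw document
#'
#' Reads a PDF or UTF-8 plain-text file and returns its text with Unicode
#' hygiene applied (ligatures expanded, soft hyphens dropped). The file
#' extension decides the reader: `.pdf` goes through [pdf_extract_text()],
#' everything else is read as plain text.
#'
#' @param path Path to a `.pdf` or text file.
#' @param doc_id Document identifier; defaults to the file name without
#'   extension.
#' @return A `raw_document`: list with `doc_id`, `source_path`,
#'   `source_kind` (`"pdf"` or `"text"`), `raw_text`, `page_count`
#'   (0 for text sources).
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines("Methods\n\nMice were used.", tf)
#' doc <- load_document(tf)
#' doc$source_kind
#' @export
load_document <- function(path, doc_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vivomine_ingest_error")
  }
  doc_id <- doc_id %||% sub("\\.[^.]+$", "", basename(path))
  is_pdf <- grepl("\\.pdf$", path, ignore.case = TRUE)
  if (is_pdf) {
    ext <- pdf_extract_text(path)
    text <- ext$text
    page_count <- ext$page_count
  } else {
    raw <- readBin(path, "raw", n = max(file.info(path)$size, 0))
    text <- rawToChar(raw)
    Encoding(text) <- "UTF-8"
    if (!validUTF8(text)) {
      warn(sprintf("invalid UTF-8 in %s; bad bytes replaced", path))
      text <- iconv(rawToChar(raw), from = "UTF-8", to = "UTF-8", sub = "�")
    }
    page_count <- 0L
  }
  text <- expand_ligatures(text)
  if (!nzchar(trimws(text))) {
    abort(sprintf("no text could be extracted from %s (empty or image-only file)",
                  path),
          class = "vivomine_empty_text_error")
  }
  structure(
    list(doc_id = doc_id, source_path = path,
         source_kind = if (is_pdf) "pdf" else "text",
         raw_text = text, page_count = as.integer(page_count)),
    class = "raw_document"
  )
}

#' @export
print.raw_document <- function(x, ...) {
  cat(sprintf("<raw_document> %s (%s, %d chars, %d pages)\n",
              x$doc_id, x$source_kind, nchar(x$raw_text), x$page_count))
  invisible(x)
}

expand_ligatures <- function(text) {
  # typographic ligatures and soft hyphens from PDF extraction
  text <- stringr::str_replace_all(text, c(
    "ﬀ" = "ff", "ﬁ" = "fi", "ﬂ" = "fl",
    "ﬃ" = "ffi", "ﬄ" = "ffl", "­" = ""))
  text
}

#' Normalize extracted text
#'
#' Repairs line-break hyphenation (`"randomi-\\nzation"` becomes
#' `"randomization"`), collapses runs of spaces and single line breaks to
#' one space, and preserves paragraph breaks (blank lines) as a single
#' newline. Case is untouched, so section headings keep their styling.
#'
#' @param raw_text Any character scalar.
#' @return Normalized character scalar.
#' @examples
#' normalize_text("blin-\nded")
#' normalize_text("a  b\n\nc")
#' @export
normalize_text <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1)
  if (is.na(raw_text) || !nzchar(raw_text)) return(if (is.na(raw_text)) "" else raw_text)
  x <- expand_ligatures(raw_text)
  x <- stringr::str_replace_all(x, "\r\n?", "\n")
  # hyphen at end of line joining two word halves
  x <- stringr::str_replace_all(x, "([[:alpha:]])-[ \t]*\n[ \t]*([[:alpha:]])", "\\1\\2")
  # mark paragraph breaks with a sentinel, flatten other breaks to spaces
  x <- stringr::str_replace_all(x, "[ \t]*\n[ \t]*\n[ \t\n]*", "\x01")
  x <- stringr::str_replace_all(x, "[ \t]*\n[ \t]*", " ")
  x <- stringr::str_replace_all(x, "[ \t]+", " ")
  x <- stringr::str_replace_all(x, "\x01", "\n")
  stringr::str_trim(x)
}

#' Cleaning rules for false-positive suppression
#'
#' A cleaning rule deletes (or blanks) every match of a phrase that would
#' otherwise trigger an item's patterns spuriously — the canonical example
#' is "random primer", molecular-biology vocabulary that collides with
#' randomization patterns. Cleaning runs once, globally, before sectioning
#' and matching.
#'
#' @param rule_id Unique rule identifier.
#' @param pattern Regular expression (matched case-insensitively).
#' @param action `"replace_with_space"` (default; keeps word boundaries
#'   intact) or `"delete_match"`.
#' @param target_item Item whose false positives the rule suppresses.
#' @param rationale Free-text note.
#' @return One-row tibble; rbind rules into a rule set.
#' @export
cleaning_rule <- function(rule_id, pattern, action = c("replace_with_space", "delete_match"),
                          target_item = NA_character_, rationale = NA_character_) {
  action <- match.arg(action)
  ok <- tryCatch({ suppressWarnings(grepl(pattern, "", perl = TRUE)); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    abort(sprintf("cleaning rule '%s': pattern does not compile: %s",
                  rule_id, pattern),
          class = "vivomine_config_error")
  }
  tibble(rule_id = rule_id, pattern = pattern, action = action,
         target_item = target_item, rationale = rationale)
}

#' @rdname cleaning_rule
#' @details `default_cleaning_rules()` ships the built-in rule set (random
#'   primer / random hexamer / husbandry-randomization phrasing and the
#'   "blinding" collision with visual-impairment vocabulary). The set is a
#'   starting point, not a closed list: extend it via a YAML rules file and
#'   [read_cleaning_rules()].
#' @export
default_cleaning_rules <- function() {
  read_cleaning_rules(system.file("extdata", "cleaning_rules.yaml",
                                  package = "vivomine", mustWork = TRUE))
}

#' Read cleaning rules from a YAML file
#'
#' The file holds a list of entries with fields `rule_id`, `pattern`,
#' optional `action`, `target_item`, `rationale`.
#'
#' @param path YAML file path.
#' @return Tibble of cleaning rules.
#' @export
read_cleaning_rules <- function(path) {
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0) {
    return(cleaning_rule("none", "(?!)")[0, ])
  }
  rules <- purrr::map(entries, function(e) {
    cleaning_rule(rule_id = e$rule_id, pattern = e$pattern,
                  action = e$action %||% "replace_with_space",
                  target_item = e$target_item %||% NA_character_,
                  rationale = e$rationale %||% NA_character_)
  })
  ids <- purrr::map_chr(rules, "rule_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate cleaning rule ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "vivomine_config_error")
  }
  bind_rows(rules)
}

#' Apply cleaning rules to text
#'
#' Every match of every rule is removed (replaced by a single space by
#' default, so surrounding word boundaries survive), case-insensitively.
#' Applying the same rules twice is a no-op.
#'
#' @param text Character scalar.
#' @param rules Tibble of cleaning rules, e.g. [default_cleaning_rules()].
#' @return Cleaned text.
#' @examples
#' apply_cleaning("cDNA was made with a random primer kit",
#'                default_cleaning_rules())
#' @export
apply_cleaning <- function(text, rules = default_cleaning_rules()) {
  stopifnot(is.character(text), length(text) == 1)
  for (i in seq_len(nrow(rules))) {
    repl <- if (rules$action[[i]] == "delete_match") "" else " "
    text <- stringr::str_replace_all(
      text, stringr::regex(rules$pattern[[i]], ignore_case = TRUE), repl)
  }
  text
}
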