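# Pattern matching against scoped text: one hit per non-suppressed match,
# one extraction record per document, one table row per paper.

#' Match one item's patterns against scoped text
#'
#' Finds every match of the item's positive patterns, then drops matches
#' that have any of the item's negative patterns within a +/-200-character
#' window (local-context suppression without sentence segmentation, which
#' is unreliable on reflowed PDF text). Hits are ordered by start offset,
#' longer match first on ties.
#'
#' @param text Scoped text (already cleaned and normalized).
#' @param item One library row: list with `item_id`, `patterns`,
#'   `negative_patterns`.
#' @param section Label stored with each hit (e.g. `"methods"`).
#' @param window Suppression window radius in characters.
#' @return Tibble of hits: `item_id`, `pattern_id`, `section`, `start`,
#'   `end` (0-based half-open offsets into `text`), `matched_text`,
#'   `category`.
#' @export
match_item <- function(text, item, section = NA_character_, window = 200L) {
  stopifnot(is.character(text), length(text) == 1)
  pats <- if (is.data.frame(item$patterns)) item$patterns else item$patterns[[1]]
  neg <- unlist(item$negative_patterns)
  empty <- tibble(item_id = character(0), pattern_id = character(0),
                  section = character(0), start = integer(0), end = integer(0),
                  matched_text = character(0), category = character(0))
  if (!nzchar(text)) return(empty)

  hits <- purrr::pmap(pats, function(pattern_id, pattern, category) {
    loc <- stringr::str_locate_all(
      text, stringr::regex(pattern, ignore_case = TRUE))[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble(
      item_id = item$item_id,
      pattern_id = pattern_id,
      section = section,
      start = as.integer(loc[, "start"] - 1L),
      end = as.integer(loc[, "end"]),
      matched_text = stringr::str_sub(text, loc[, "start"], loc[, "end"]),
      category = category %||% NA_character_
    )
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) return(empty)

  if (length(neg) > 0) {
    neg_spans <- purrr::map(neg, function(np) {
      stringr::str_locate_all(text, stringr::regex(np, ignore_case = TRUE))[[1]]
    })
    neg_spans <- do.call(rbind, neg_spans)
    if (!is.null(neg_spans) && nrow(neg_spans) > 0) {
      keep <- vapply(seq_len(nrow(hits)), function(i) {
        lo <- hits$start[i] - window
        hi <- hits$end[i] + window
        # suppressed when any negative match intersects the window
        !any(neg_spans[, "start"] - 1L < hi & neg_spans[, "end"] > lo)
      }, logical(1))
      hits <- hits[keep, , drop = FALSE]
    }
  }
  arrange(hits, .data$start, dplyr::desc(.data$end), .data$pattern_id)
}

# raw/plain input -> cleaned, sectioned document
prepare_document <- function(doc, rules = default_cleaning_rules(),
                             headings = default_headings()) {
  if (inherits(doc, "sectioned_document")) return(doc)
  if (inherits(doc, "raw_document")) {
    text <- apply_cleaning(normalize_text(doc$raw_text), rules)
    return(segment_sections(text, headings, doc_id = doc$doc_id,
                            normalize = FALSE))
  }
  stopifnot(is.character(doc), length(doc) == 1)
  segment_sections(apply_cleaning(normalize_text(doc), rules), headings,
                   normalize = FALSE)
}

#' Extract all items from one document
#'
#' Runs every library item against its scoped text
#' (methods for experimental parameters plus randomization, blinding and
#' animal welfare; full text minus references for the remaining
#' risk-of-bias items). For categorical items the value is the category of
#' the earliest hit in document order.
#'
#' @param doc A `sectioned_document` (see [segment_sections()]); cleaning
#'   must already have been applied. [extract_corpus()] handles raw
#'   documents end to end.
#' @param library An `item_library` ([default_item_library()]).
#' @param allow_fallback When the methods section is missing, match
#'   methods-scoped items against the full body (flagged on the record).
#' @return An `extraction_record`: list with `doc_id`, `items` (tibble of
#'   item_id, detected, value), `hits` (tibble with provenance), and
#'   `methods_fallback_used`.
#' @export
extract_document <- function(doc, library = default_item_library(),
                             allow_fallback = TRUE) {
  stopifnot(inherits(doc, "sectioned_document"))
  fallback <- FALSE
  per_item <- purrr::map(seq_len(nrow(library)), function(i) {
    item <- as.list(library[i, ])
    txt <- scope_text(doc, item$scope, allow_fallback = allow_fallback)
    if (isTRUE(attr(txt, "fallback_used"))) fallback <<- TRUE
    hits <- match_item(txt, item, section = item$scope)
    value <- if (item$value_mode == "categorical" && nrow(hits) > 0)
      hits$category[[1]] else NA_character_
    list(summary = tibble(item_id = item$item_id,
                          detected = nrow(hits) > 0,
                          value = value),
         hits = hits)
  })
  structure(
    list(doc_id = doc$doc_id,
         items = bind_rows(purrr::map(per_item, "summary")),
         hits = bind_rows(purrr::map(per_item, "hits")),
         methods_fallback_used = fallback),
    class = "extraction_record"
  )
}

#' @export
print.extraction_record <- function(x, ...) {
  cat(sprintf("<extraction_record> %s: %d/%d items detected%s\n", x$doc_id,
              sum(x$items$detected), nrow(x$items),
              if (x$methods_fallback_used) " (methods fallback)" else ""))
  invisible(x)
}

record_to_row <- function(rec) {
  flags <- stats::setNames(as.list(rec$items$detected), rec$items$item_id)
  cats <- rec$items[rec$items$item_id %in% categorical_items(), ]
  vals <- stats::setNames(as.list(cats$value), paste0(cats$item_id, "_value"))
  tibble(doc_id = rec$doc_id, !!!flags, !!!vals,
         methods_fallback_used = rec$methods_fallback_used)
}

#' Extract a corpus into a one-row-per-paper table
#'
#' Accepts raw documents ([load_document()]), pre-sectioned documents, or
#' plain text strings; raw input is normalized, cleaned and sectioned
#' first. The result has one row per document in input order: a logical
#' detection column per item, a `<item>_value` column for each categorical
#' item, and the methods-fallback flag. Running the same corpus twice
#' yields identical tables.
#'
#' @param docs List of documents. Plain character vectors are accepted and
#'   named by position (`doc_1`, ...) unless the vector is named.
#' @param library An `item_library`.
#' @param cleaning_rules Cleaning rule set applied before sectioning.
#' @param keep_hits Add a `hits` list-column with full match provenance
#'   (needed by [discrepancy_report()]).
#' @param allow_fallback See [extract_document()].
#' @return Tibble; one row per document.
#' @export
extract_corpus <- function(docs, library = default_item_library(),
                           cleaning_rules = default_cleaning_rules(),
                           keep_hits = FALSE, allow_fallback = TRUE) {
  docs <- as_document_list(docs)
  ids <- purrr::map_chr(docs, doc_id_of)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate doc_id in corpus: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "vivomine_config_error")
  }
  recs <- purrr::map(docs, function(d) {
    extract_document(prepare_document(d, cleaning_rules),
                     library, allow_fallback = allow_fallback)
  })
  out <- bind_rows(purrr::map(recs, record_to_row))
  if (nrow(out) == 0) out <- empty_extraction_table(library)
  if (keep_hits) out$hits <- purrr::map(recs, "hits")
  out
}

#' Extract at abstract level
#'
#' Same schema as [extract_corpus()], but every item is matched against
#' the abstract only — used to quantify how often parameters reported in
#' the full text also surface in the abstract.
#'
#' @inheritParams extract_corpus
#' @return Tibble; one row per document (no fallback column semantics:
#'   `methods_fallback_used` is always `FALSE` at abstract scope).
#' @export
extract_abstracts <- function(docs, library = default_item_library(),
                              cleaning_rules = default_cleaning_rules(),
                              keep_hits = FALSE) {
  docs <- as_document_list(docs)
  ids <- purrr::map_chr(docs, doc_id_of)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate doc_id in corpus: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "vivomine_config_error")
  }
  recs <- purrr::map(docs, function(d) {
    sd <- prepare_document(d, cleaning_rules)
    abs_text <- scope_text(sd, "abstract")
    per_item <- purrr::map(seq_len(nrow(library)), function(i) {
      item <- as.list(library[i, ])
      hits <- match_item(abs_text, item, section = "abstract")
      value <- if (item$value_mode == "categorical" && nrow(hits) > 0)
        hits$category[[1]] else NA_character_
      list(summary = tibble(item_id = item$item_id,
                            detected = nrow(hits) > 0, value = value),
           hits = hits)
    })
    structure(
      list(doc_id = sd$doc_id,
           items = bind_rows(purrr::map(per_item, "summary")),
           hits = bind_rows(purrr::map(per_item, "hits")),
           methods_fallback_used = FALSE),
      class = "extraction_record")
  })
  out <- bind_rows(purrr::map(recs, record_to_row))
  if (nrow(out) == 0) out <- empty_extraction_table(library)
  if (keep_hits) out$hits <- purrr::map(recs, "hits")
  out
}

empty_extraction_table <- function(library) {
  flags <- stats::setNames(
    rep(list(logical(0)), nrow(library)), library$item_id)
  vals <- stats::setNames(
    rep(list(character(0)), length(categorical_items())),
    paste0(categorical_items(), "_value"))
  tibble(doc_id = character(0), !!!flags, !!!vals,
         methods_fallback_used = logical(0))
}

as_document_list <- function(docs) {
  if (inherits(docs, c("raw_document", "sectioned_document"))) return(list(docs))
  if (is.character(docs)) {
    nms <- names(docs) %||% sprintf("doc_%d", seq_along(docs))
    return(purrr::map2(unname(docs), nms, text_document))
  }
  stopifnot(is.list(docs))
  docs
}

# wrap an in-memory string as a raw document so it flows through the same
# normalize -> clean -> section pipeline as file input
text_document <- function(text, doc_id) {
  structure(
    list(doc_id = doc_id, source_path = NA_character_, source_kind = "text",
         raw_text = text, page_count = 0L),
    class = "raw_document")
}

doc_id_of <- function(doc) doc$doc_id

#' Write an extraction table to CSV or JSON lines
#'
#' CSV drops the `hits` list-column; JSONL keeps full hit provenance, one
#' document per line.
#'
#' @param extractions Tibble from [extract_corpus()].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_extractions <- function(extractions, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    flat <- extractions[, setdiff(names(extractions), "hits")]
    readr::write_csv(flat, path, na = "")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(extractions))) {
      row <- as.list(extractions[i, ])
      row$hits <- if (!is.null(row$hits)) row$hits[[1]] else NULL
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null",
                                  digits = NA),
                 con, useBytes = TRUE)
    }
  }
  invisible(path)
}
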