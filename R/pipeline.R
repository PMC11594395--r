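# End-to-end pipeline: directory of documents -> extraction table + run
# manifest, with per-document failure isolation, plus the human-review
# discrepancy report.

#' Run the full extraction pipeline over a directory
#'
#' Reads every `.pdf` and `.txt` file in `input_dir`, normalizes, cleans,
#' sections and extracts each document, and returns the extraction table
#' together with a run manifest. Failures are isolated per document: a
#' file with no extractable text gets an `empty_text` status and the rest
#' of the corpus proceeds.
#'
#' @param input_dir Directory of documents.
#' @param library An `item_library`, or a path to a YAML library file.
#' @param cleaning_rules Cleaning rule set or path to a YAML rules file.
#' @param out_prefix If set, writes `<prefix>_extractions.csv` and
#'   `<prefix>_manifest.json`.
#' @param abstract_level Also compute the abstract-scope extraction table
#'   (returned as `$abstracts`).
#' @param keep_hits Keep full hit provenance on the extraction table.
#' @return A `pipeline_result`: list with `extractions`, `manifest`
#'   (tibble: file, doc_id, md5, status in ok / fallback_methods /
#'   empty_text), optional `abstracts`, and run metadata (`version`,
#'   `library_hash`, `cleaning_hash`, `timestamp`).
#' @export
run_pipeline <- function(input_dir, library = default_item_library(),
                         cleaning_rules = default_cleaning_rules(),
                         out_prefix = NULL, abstract_level = FALSE,
                         keep_hits = FALSE) {
  if (is.character(library)) {
    library_hash <- unname(tools::md5sum(library))
    library <- compile_library(library)
  } else {
    library_hash <- unname(tools::md5sum(
      system.file("extdata", "item_library.yaml", package = "vivomine")))
  }
  if (is.character(cleaning_rules)) {
    cleaning_hash <- unname(tools::md5sum(cleaning_rules))
    cleaning_rules <- read_cleaning_rules(cleaning_rules)
  } else {
    cleaning_hash <- unname(tools::md5sum(
      system.file("extdata", "cleaning_rules.yaml", package = "vivomine")))
  }
  files <- sort(list.files(input_dir, pattern = "\\.(pdf|txt)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("no .pdf or .txt documents in %s", input_dir),
          class = "vivomine_corpus_error")
  }
  loaded <- purrr::map(files, function(f) {
    tryCatch(list(doc = load_document(f), status = "ok"),
             vivomine_empty_text_error = function(e)
               list(doc = NULL, status = "empty_text"),
             vivomine_ingest_error = function(e)
               list(doc = NULL, status = "empty_text"))
  })
  docs <- purrr::compact(purrr::map(loaded, "doc"))
  if (length(docs) == 0) {
    abort(sprintf("no readable documents in %s", input_dir),
          class = "vivomine_corpus_error")
  }
  extractions <- extract_corpus(docs, library, cleaning_rules,
                                keep_hits = keep_hits)
  status <- purrr::map_chr(loaded, "status")
  ids <- purrr::map_chr(loaded, function(l)
    if (is.null(l$doc)) NA_character_ else l$doc$doc_id)
  fallback <- extractions$methods_fallback_used[match(ids, extractions$doc_id)]
  status[!is.na(fallback) & fallback & status == "ok"] <- "fallback_methods"
  manifest <- tibble(file = basename(files), doc_id = ids,
                     md5 = unname(tools::md5sum(files)), status = status)
  out <- structure(
    list(extractions = extractions, manifest = manifest,
         version = as.character(utils::packageVersion("vivomine")),
         library_hash = library_hash, cleaning_hash = cleaning_hash,
         timestamp = format(Sys.time(), tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")),
    class = "pipeline_result")
  if (abstract_level) {
    out$abstracts <- extract_abstracts(docs, library, cleaning_rules)
  }
  if (!is.null(out_prefix)) {
    write_extractions(extractions, paste0(out_prefix, "_extractions.csv"))
    jsonlite::write_json(
      list(version = out$version, library_hash = out$library_hash,
           cleaning_hash = out$cleaning_hash, timestamp = out$timestamp,
           documents = manifest),
      paste0(out_prefix, "_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d files: %s\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$status)),
                            table(x$manifest$status)), collapse = ", ")))
  invisible(x)
}

#' Per-document disagreement listing for manual review
#'
#' One row per (document, item) pair where machine and gold disagree, with
#' the machine's match provenance (section, pattern id, matched text) for
#' false positives and `"no match"` for false negatives — the listing a
#' human reviewer works through when the tool replaces one reader.
#'
#' @param extractions Extraction table from
#'   `extract_corpus(..., keep_hits = TRUE)`; works without hits, with
#'   empty provenance columns.
#' @param gold Gold tibble covering all extracted documents.
#' @param mode Scoring mode, as in [confusion()].
#' @return Tibble: `doc_id`, `item_id`, `machine`, `gold`, `section`,
#'   `pattern_id`, `matched_text`.
#' @export
discrepancy_report <- function(extractions, gold,
                               mode = c("detection", "value_match")) {
  mode <- match.arg(mode)
  missing <- setdiff(extractions$doc_id, gold$doc_id)
  if (length(missing) > 0) {
    abort(sprintf("documents missing from gold standard: %s",
                  paste(missing, collapse = ", ")),
          class = "vivomine_eval_error")
  }
  g <- gold[match(extractions$doc_id, gold$doc_id), ]
  rows <- list()
  for (i in seq_len(nrow(extractions))) {
    hits <- if ("hits" %in% names(extractions)) extractions$hits[[i]] else NULL
    for (item in item_schema()$item_id) {
      truth <- as.integer(g[[item]][i])
      if (is.na(truth)) next
      pred <- isTRUE(extractions[[item]][i])
      if (mode == "value_match" && item %in% categorical_items() &&
          !is.null(gold[[paste0(item, "_value")]])) {
        gv <- as.character(g[[paste0(item, "_value")]][i])
        ev <- as.character(extractions[[paste0(item, "_value")]][i])
        if (pred && truth == 1L && (is.na(ev) || is.na(gv) || ev != gv)) {
          pred <- FALSE
        }
      }
      if (pred == (truth == 1L)) next
      h <- if (!is.null(hits)) hits[hits$item_id == item, ] else NULL
      rows[[length(rows) + 1]] <- tibble(
        doc_id = extractions$doc_id[i], item_id = item,
        machine = pred, gold = truth == 1L,
        section = if (pred && !is.null(h) && nrow(h) > 0)
          h$section[1] else NA_character_,
        pattern_id = if (pred && !is.null(h) && nrow(h) > 0)
          h$pattern_id[1] else NA_character_,
        matched_text = if (pred && !is.null(h) && nrow(h) > 0)
          h$matched_text[1] else "no match")
    }
  }
  if (length(rows) == 0) {
    return(tibble(doc_id = character(0), item_id = character(0),
                  machine = logical(0), gold = logical(0),
                  section = character(0), pattern_id = character(0),
                  matched_text = character(0)))
  }
  bind_rows(rows)
}
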