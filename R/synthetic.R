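# Synthetic-publication generator: mock IMRaD articles with known per-item
# ground truth. The generator is the package's test bed — real corpora of
# full-text PDFs cannot be redistributed, so every end-to-end property
# (scope correctness, cleaning, calibrated sensitivity recovery) is
# demonstrated on corpora whose truth is known by construction.

#' Default per-item reporting prevalence
#'
#' The generator's default prevalence profile mirrors a training corpus of
#' 45 motor neuron disease publications: near-universal species and model
#' reporting, moderate sex and outcome reporting, and sparse risk-of-bias
#' reporting (e.g. sample-size calculation 27%, ARRIVE 29%).
#'
#' @return Named numeric vector over the 13 items, values in `[0, 1]`.
#' @export
default_prevalence <- function() {
  c(species = 1.00, sex = 0.87, disease_model = 1.00,
    outcome_histology = 0.82, outcome_behaviour = 0.73,
    outcome_imaging = 0.02, randomization = 0.58, blinding = 0.47,
    animal_welfare = 0.98, conflict_of_interest = 0.96,
    sample_size_calculation = 0.27, arrive_guidelines = 0.29,
    data_availability = 0.69)
}

#' Specify a synthetic corpus
#'
#' @param n_docs Number of documents.
#' @param seed Root seed; the same spec and seed give a byte-identical
#'   corpus. Per-document substreams are derived from it.
#' @param prevalence Named vector of per-item gold-positive fractions in
#'   `[0, 1]`; quota-sampled, so exactly `round(n_docs * p)` documents are
#'   positive for each item.
#' @param distractor_rate Fraction of documents that receive a
#'   cleaning-rule distractor phrase ("random primer", ...) in methods.
#' @param dialect_weights Named weights over the heading dialects of
#'   [heading_dialects()].
#' @param layout `"paragraph"` (one line per paragraph), `"sentences"`
#'   (one line per sentence) or `"wrapped"` (hard-wrapped at 80 columns).
#' @param error_injection Optional `list(miss_rate =, false_alarm_rate =,
#'   items =)`. Quota-based, like prevalence: with miss rate m, exactly
#'   `round(m * n_positives)` gold-positive statements per item are
#'   planted as undetectable paraphrases (the label stays positive); with
#'   false-alarm rate f, exactly `round(f * n_negatives)` gold-negative
#'   documents receive a library-matching but semantically negative
#'   sentence (the label stays negative). `items = NULL` targets all 13
#'   items.
#' @param abstract_echo Echo species / model / outcome statements into the
#'   abstract of positive documents at 97%, sex at 3% (abstracts rarely
#'   state animal sex).
#' @param output_kind `"text"` or `"pdf"`; used by [write_corpus()].
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_docs = 45, seed = 1,
                       prevalence = default_prevalence(),
                       distractor_rate = 0.3,
                       dialect_weights = NULL,
                       layout = c("paragraph", "sentences", "wrapped"),
                       error_injection = NULL,
                       abstract_echo = TRUE,
                       output_kind = c("text", "pdf")) {
  layout <- match.arg(layout)
  output_kind <- match.arg(output_kind)
  stopifnot(n_docs >= 1, all(prevalence >= 0 & prevalence <= 1),
            distractor_rate >= 0 && distractor_rate <= 1)
  full <- default_prevalence()
  full[names(prevalence)] <- prevalence
  missing_items <- setdiff(item_schema()$item_id, names(full))
  if (length(missing_items) > 0) {
    abort(sprintf("prevalence missing items: %s",
                  paste(missing_items, collapse = ", ")),
          class = "vivomine_config_error")
  }
  dials <- names(heading_dialects())
  w <- rep(1, length(dials)); names(w) <- dials
  if (!is.null(dialect_weights)) {
    w[] <- 0
    w[names(dialect_weights)] <- dialect_weights
  }
  ei <- error_injection %||% list(miss_rate = 0, false_alarm_rate = 0,
                                  items = NULL)
  ei$miss_rate <- ei$miss_rate %||% 0
  ei$false_alarm_rate <- ei$false_alarm_rate %||% 0
  stopifnot(ei$miss_rate >= 0 && ei$miss_rate <= 1,
            ei$false_alarm_rate >= 0 && ei$false_alarm_rate <= 1)
  structure(
    list(n_docs = as.integer(n_docs), seed = as.integer(seed),
         prevalence = full[item_schema()$item_id],
         distractor_rate = distractor_rate, dialect_weights = w,
         layout = layout, error_injection = ei,
         abstract_echo = abstract_echo, output_kind = output_kind),
    class = "synth_spec")
}

#' Produce one planted statement
#'
#' Looks up the template bank for an item and returns a natural-language
#' sentence expressing it. Used by [generate_corpus()] and directly in
#' fixture construction.
#'
#' @param item_id One of the 13 item ids.
#' @param variant_index 1-based template index (wraps around the bank).
#' @param kind `"detectable"` (fires the default library),
#'   `"undetectable"` (paraphrase the library misses) or `"false_alarm"`
#'   (matches the library but is semantically negative).
#' @param category Category for categorical items (e.g. `"mouse"`);
#'   defaults to the first category in the bank.
#' @return Character scalar.
#' @export
plant_statement <- function(item_id, variant_index = 1,
                            kind = c("detectable", "undetectable", "false_alarm"),
                            category = NULL) {
  kind <- match.arg(kind)
  tm <- synth_templates()
  if (!item_id %in% names(tm)) {
    abort(sprintf("unknown item: %s", item_id), class = "vivomine_config_error")
  }
  bank <- tm[[item_id]][[kind]]
  if (kind == "detectable" && is.list(bank)) {
    category <- category %||% names(bank)[1]
    if (!category %in% names(bank)) {
      abort(sprintf("unknown category '%s' for item %s", category, item_id),
            class = "vivomine_config_error")
    }
    bank <- bank[[category]]
  }
  bank[[((variant_index - 1L) %% length(bank)) + 1L]]
}

item_categories <- function(item_id) {
  bank <- synth_templates()[[item_id]]$detectable
  if (is.list(bank)) names(bank) else NA_character_
}

#' Generate a synthetic corpus
#'
#' Builds `n_docs` mock IMRaD publications under the given spec. Each
#' document has abstract / introduction / methods / results / discussion /
#' references blocks with a sampled heading dialect; positive statements
#' are planted in each item's policy section (methods for methods-scoped
#' items and sample-size calculation, end matter for conflict of interest,
#' ARRIVE and data availability); the references block always contains
#' decoy citations loaded with item vocabulary that must never produce
#' hits.
#'
#' @param spec A [synth_spec()].
#' @return A `synthetic_corpus`: list with `docs` (tibble: doc_id, text,
#'   dialect, layout), `gold` (one row per doc, item labels and
#'   categorical values), `manifest` (tibble of every planted statement,
#'   distractor and decoy with its section and detectability), `spec`.
#' @export
generate_corpus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  tm <- synth_templates()
  items <- item_schema()$item_id
  n <- spec$n_docs
  set.seed(spec$seed)

  # quota sampling: exactly round(n * p) positives per item
  pos <- sapply(items, function(it) {
    k <- round_half_up(n * spec$prevalence[[it]])
    v <- logical(n)
    if (k > 0) v[sample.int(n, k)] <- TRUE
    v
  })
  pos <- matrix(pos, nrow = n, dimnames = list(NULL, items))

  # quota-based error injection: exact counts, so calibration corpora
  # realize the injected rates up to rounding
  ei <- spec$error_injection
  target <- ei$items %||% items
  miss <- matrix(FALSE, n, length(items), dimnames = list(NULL, items))
  falarm <- matrix(FALSE, n, length(items), dimnames = list(NULL, items))
  for (it in intersect(target, items)) {
    p_idx <- which(pos[, it]); n_idx <- which(!pos[, it])
    k_miss <- round_half_up(length(p_idx) * ei$miss_rate)
    if (k_miss > 0) miss[sample(p_idx, k_miss), it] <- TRUE
    k_fa <- round_half_up(length(n_idx) * ei$false_alarm_rate)
    if (k_fa > 0) falarm[sample(n_idx, k_fa), it] <- TRUE
  }
  doc_seeds <- sample.int(.Machine$integer.max - 1L, n)

  docs <- vector("list", n)
  gold <- vector("list", n)
  manifest <- vector("list", n)
  dials <- heading_dialects()

  for (i in seq_len(n)) {
    set.seed(doc_seeds[i])
    doc_id <- sprintf("SYN%04d", i)
    dialect <- sample(names(dials), 1, prob = spec$dialect_weights)
    filler <- sample(filler_sentences())
    sec <- list(abstract = filler[1], introduction = filler[2:3],
                methods = character(0), results = filler[4:5],
                discussion = filler[6], references = reference_decoys())
    man <- list()
    vals <- list(species_value = NA_character_, sex_value = NA_character_,
                 disease_model_value = NA_character_)

    for (it in items) {
      place <- tm[[it]]$section
      if (pos[i, it]) {
        cat_i <- if (it %in% categorical_items())
          sample(item_categories(it), 1) else NULL
        if (!is.null(cat_i)) vals[[paste0(it, "_value")]] <- cat_i
        missed <- miss[i, it]
        kind <- if (missed) "undetectable" else "detectable"
        vi <- sample.int(10L, 1)
        stmt <- plant_statement(it, vi, kind = kind, category = cat_i)
        sec[[place]] <- c(sec[[place]], stmt)
        man[[length(man) + 1]] <- tibble(
          doc_id = doc_id, item_id = it,
          kind = if (missed) "miss_paraphrase" else "positive",
          section = place, sentence = stmt, detectable = !missed,
          category = cat_i %||% NA_character_)
        if (spec$abstract_echo && !missed) {
          echo <- tm[[it]]$echo
          echo_rate <- if (it == "sex") 0.03 else 0.97
          if (!is.null(echo) && stats::runif(1) < echo_rate) {
            e <- if (is.list(echo)) echo[[cat_i]] else echo
            sec$abstract <- c(sec$abstract, e)
            man[[length(man) + 1]] <- tibble(
              doc_id = doc_id, item_id = it, kind = "abstract_echo",
              section = "abstract", sentence = e, detectable = TRUE,
              category = cat_i %||% NA_character_)
          }
        }
      } else if (falarm[i, it]) {
        stmt <- plant_statement(it, sample.int(10L, 1), kind = "false_alarm")
        sec[[place]] <- c(sec[[place]], stmt)
        man[[length(man) + 1]] <- tibble(
          doc_id = doc_id, item_id = it, kind = "false_alarm",
          section = place, sentence = stmt, detectable = TRUE,
          category = NA_character_)
      }
    }

    if (stats::runif(1) < spec$distractor_rate) {
      d <- sample(distractor_phrases(), 1)
      sec$methods <- c(sec$methods, d)
      man[[length(man) + 1]] <- tibble(
        doc_id = doc_id, item_id = "randomization", kind = "distractor",
        section = "methods", sentence = d, detectable = FALSE,
        category = NA_character_)
    }
    # keep planted order unpredictable but reproducible
    sec$methods <- sample(c(sec$methods, filler[7:8]))
    sec$discussion <- sample(c(sec$discussion, filler[9]))

    man[[length(man) + 1]] <- tibble(
      doc_id = doc_id, item_id = NA_character_, kind = "reference_decoy",
      section = "references",
      sentence = reference_decoys(), detectable = FALSE,
      category = NA_character_)

    docs[[i]] <- tibble(doc_id = doc_id,
                        text = build_doc_text(sec, dials[[dialect]],
                                              spec$layout),
                        dialect = dialect, layout = spec$layout)
    gold[[i]] <- tibble(doc_id = doc_id,
                        !!!stats::setNames(as.list(as.integer(pos[i, items])),
                                           items),
                        !!!vals)
    manifest[[i]] <- bind_rows(man)
  }

  structure(
    list(docs = bind_rows(docs), gold = bind_rows(gold),
         manifest = bind_rows(manifest), spec = spec),
    class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d documents (seed %d, layout %s)\n",
              nrow(x$docs), x$spec$seed, x$spec$layout))
  invisible(x)
}

build_doc_text <- function(sec, headings, layout) {
  para <- function(sentences) {
    if (length(sentences) == 0) return(character(0))
    switch(layout,
      paragraph = paste(sentences, collapse = " "),
      sentences = sentences,
      wrapped = strwrap(paste(sentences, collapse = " "), width = 80))
  }
  blocks <- character(0)
  for (s in c("abstract", "introduction", "methods", "results",
              "discussion", "references")) {
    h <- headings[[s]]
    body <- if (s == "references") sec$references else para(sec[[s]])
    block <- c(if (!is.na(h)) h, "", body, "")
    blocks <- c(blocks, block)
  }
  paste(blocks, collapse = "\n")
}

#' Write a synthetic corpus to disk
#'
#' Emits one file per document (`SYN0001.txt`, or `.pdf` when the spec's
#' `output_kind` is `"pdf"`), `gold.csv`, and `manifest.jsonl`. Output is
#' byte-identical across runs for the same corpus.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @param output_kind Override the spec's output kind.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, output_kind = NULL) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  kind <- output_kind %||% corpus$spec$output_kind
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$docs))) {
    id <- corpus$docs$doc_id[i]
    text <- corpus$docs$text[i]
    if (kind == "pdf") {
      pdf_write_text(text, file.path(dir, paste0(id, ".pdf")))
    } else {
      writeLines(text, file.path(dir, paste0(id, ".txt")), useBytes = TRUE)
    }
  }
  readr::write_csv(corpus$gold, file.path(dir, "gold.csv"), na = "")
  con <- file(file.path(dir, "manifest.jsonl"), open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$manifest))) {
    writeLines(jsonlite::toJSON(as.list(corpus$manifest[i, ]),
                                auto_unbox = TRUE, na = "null", digits = NA),
               con, useBytes = TRUE)
  }
  invisible(dir)
}
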