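test_that("match_item finds pattern hits with faithful provenance", {
  lib <- default_item_library()
  rand <- lib_item(lib, "randomization")
  hits <- match_item("mice were randomly allocated to groups", rand)
  expect_gte(nrow(hits), 1L)
  # oracle: an independent base-R scan over the same pattern list
  pats <- rand$patterns[[1]]$pattern
  oracle_n <- sum(vapply(pats, function(p)
    length(gregexpr(p, "mice were randomly allocated to groups",
                    ignore.case = TRUE, perl = TRUE)[[1]]) *
      (regexpr(p, "mice were randomly allocated to groups",
               ignore.case = TRUE, perl = TRUE) > 0), integer(1)))
  expect_equal(nrow(hits), oracle_n)
  # matched_text equals the text at the recorded span (0-based half-open)
  txt <- "mice were randomly allocated to groups"
  for (i in seq_len(nrow(hits))) {
    expect_equal(substr(txt, hits$start[i] + 1L, hits$end[i]),
                 hits$matched_text[i])
  }
  expect_equal(nrow(match_item("", rand)), 0L)
  expect_equal(nrow(match_item("animals were blinded", rand)), 0L)
})

test_that("negative patterns suppress hits within the local window only", {
  item <- list(item_id = "demo",
               patterns = list(tibble::tibble(
                 pattern_id = "p1", pattern = "\\btarget\\b",
                 category = NA_character_)),
               negative_patterns = list("veto"))
  near <- paste0("xx veto ", strrep("a ", 20), "target yy")
  expect_equal(nrow(match_item(near, item)), 0L)
  far <- paste0("veto ", strrep("a ", 150), "target")
  expect_equal(nrow(match_item(far, item)), 1L)
  # window radius is configurable
  expect_equal(nrow(match_item(far, item, window = 500L)), 0L)
})

test_that("hits are ordered by start with the longest match first on ties", {
  lib <- default_item_library()
  hits <- match_item("Male and female animals were used.", lib_item(lib, "sex"))
  expect_equal(hits$category[1], "both")
  expect_true(!is.unsorted(hits$start))
})

test_that("extract_document applies scopes and records categorical values", {
  txt <- tiny_article(
    methods = paste("Adult C57BL/6J mice were obtained from the breeding colony.",
                    "Animals were randomly allocated to treatment groups.",
                    "Scoring was carried out in a blinded fashion."))
  rec <- extract_document(vivomine:::prepare_document(txt))
  items <- rec$items
  expect_true(items$detected[items$item_id == "species"])
  expect_equal(items$value[items$item_id == "species"], "mouse")
  expect_true(items$detected[items$item_id == "randomization"])
  expect_true(items$detected[items$item_id == "blinding"])
  expect_true(items$detected[items$item_id == "conflict_of_interest"])
  expect_false(items$detected[items$item_id == "outcome_imaging"])
  expect_false(rec$methods_fallback_used)
  # detected is true iff hits exist
  for (it in items$item_id) {
    expect_equal(items$detected[items$item_id == it],
                 any(rec$hits$item_id == it))
  }
})

test_that("statements only in the references block yield no hits", {
  txt <- tiny_article(
    methods = "Animals were housed under standard conditions.",
    discussion = "No end matter statements are made.",
    references = "1. Doe J. Randomized, blinded ARRIVE-compliant trial in SOD1 mice with power analysis. 2020.")
  rec <- extract_document(vivomine:::prepare_document(txt))
  expect_false(any(rec$items$detected))
})

test_that("methods-scoped statements in the discussion are ignored without fallback", {
  txt <- tiny_article(
    methods = "Standard housing was provided.",
    discussion = paste("Animals were randomly allocated to treatment groups.",
                       "The authors declare no conflict of interest."))
  rec <- extract_document(vivomine:::prepare_document(txt))
  expect_false(rec$items$detected[rec$items$item_id == "randomization"])
  # full-scope item in the discussion is found
  expect_true(rec$items$detected[rec$items$item_id == "conflict_of_interest"])
})

test_that("extract_corpus has stable shape, order and determinism", {
  corp <- generate_corpus(synth_spec(n_docs = 5, seed = 11))
  texts <- corpus_texts(corp)
  ex1 <- extract_corpus(texts)
  ex2 <- extract_corpus(texts)
  expect_identical(ex1, ex2)
  expect_equal(ex1$doc_id, corp$docs$doc_id)
  expect_equal(nrow(ex1), 5L)
  expect_true(all(item_schema()$item_id %in% names(ex1)))
  expect_true(all(c("species_value", "sex_value", "disease_model_value")
                  %in% names(ex1)))

  # duplicate ids refused before extraction
  expect_error(extract_corpus(stats::setNames(texts[c(1, 1)], c("a", "a"))),
               class = "vivomine_config_error")

  # empty corpus keeps the full header
  ex0 <- extract_corpus(character(0))
  expect_equal(nrow(ex0), 0L)
  expect_true(all(item_schema()$item_id %in% names(ex0)))
})

test_that("adding a pattern can only add hits, never remove them", {
  lib <- default_item_library()
  corp <- generate_corpus(synth_spec(n_docs = 8, seed = 21))
  texts <- corpus_texts(corp)
  base <- extract_corpus(texts, lib)
  aug <- lib
  i <- which(aug$item_id == "randomization")
  aug$patterns[[i]] <- dplyr::bind_rows(
    aug$patterns[[i]],
    tibble::tibble(pattern_id = "rand_extra", pattern = "\\bcoin toss\\b",
                   category = NA_character_))
  more <- extract_corpus(texts, aug)
  for (it in item_schema()$item_id) {
    expect_true(all(more[[it]] >= base[[it]]),
                label = sprintf("monotonicity for %s", it))
  }
})

test_that("abstract-level extraction is isolated to the abstract", {
  # species stated in methods only: full-text table detects it, the
  # abstract-level table does not
  txt <- tiny_article(methods = "Adult Wistar rats were housed in pairs.")
  full <- extract_corpus(stats::setNames(txt, "d1"))
  abs_only <- extract_abstracts(stats::setNames(txt, "d1"))
  expect_true(full$species)
  expect_false(abs_only$species)

  # species echoed in the abstract is seen by both
  txt2 <- paste("Abstract", "", "We report findings in mice.", "",
                "Methods", "", "Adult C57BL/6J mice were used.", "",
                sep = "\n")
  both <- extract_corpus(stats::setNames(txt2, "d2"))
  abs2 <- extract_abstracts(stats::setNames(txt2, "d2"))
  expect_true(both$species)
  expect_true(abs2$species)
  expect_equal(abs2$species_value, "mouse")
})

test_that("abstract echoes drive abstract-level reporting frequencies", {
  sp <- synth_spec(n_docs = 40, seed = 9)
  corp <- generate_corpus(sp)
  abs_tab <- extract_abstracts(corpus_texts(corp))
  man <- corp$manifest
  echo_docs <- unique(man$doc_id[man$kind == "abstract_echo" &
                                 man$item_id == "disease_model"])
  expect_true(all(abs_tab$disease_model[abs_tab$doc_id %in% echo_docs]))
  # sex is almost never echoed in abstracts
  sex_echo <- sum(man$kind == "abstract_echo" & man$item_id == "sex")
  sex_pos <- sum(corp$gold$sex == 1)
  expect_lt(sex_echo / sex_pos, 0.2)
})

test_that("hit provenance lies within the scoped text", {
  corp <- generate_corpus(synth_spec(n_docs = 6, seed = 13))
  lib <- default_item_library()
  for (i in seq_len(3)) {
    sd <- vivomine:::prepare_document(
      vivomine:::text_document(corp$docs$text[i], corp$docs$doc_id[i]))
    rec <- extract_document(sd)
    for (j in seq_len(nrow(rec$hits))) {
      h <- rec$hits[j, ]
      scoped <- as.character(scope_text(sd, h$section))
      expect_equal(substr(scoped, h$start + 1L, h$end), h$matched_text)
    }
  }
})

test_that("extraction tables serialize to CSV and JSONL", {
  corp <- generate_corpus(synth_spec(n_docs = 3, seed = 2))
  ex <- extract_corpus(corpus_texts(corp), keep_hits = TRUE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_extractions(ex, csv, format = "csv")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 3L)
  expect_equal(back$doc_id, ex$doc_id)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_extractions(ex, jl, format = "jsonl")
  lines <- readLines(jl)
  expect_equal(length(lines), 3L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$doc_id, ex$doc_id[1])
  expect_true(!is.null(parsed$hits))
})
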