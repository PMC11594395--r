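# Item definitions: the 13-item extraction schema and its pattern libraries.
#
# The schema (which items exist, their domain, scope and value mode) is
# fixed; the pattern libraries behind each item are swappable YAML config.
# The shipped default library is a curated reconstruction of the kind of
# phrase banks used for preclinical neuroscience corpora, not a byte-exact
# copy of any published library.

#' The 13-item extraction schema
#'
#' Returns the canonical schema: six experimental parameters (species, sex,
#' disease model and the histology / behaviour / imaging outcome
#' modalities) and seven risk-of-bias items (randomization, blinding,
#' animal welfare, conflict of interest, sample-size calculation, ARRIVE
#' guidelines, data availability). Experimental parameters and the
#' randomization / blinding / welfare items are mined from the methods
#' section; the remaining risk-of-bias items from the full text minus the
#' references. Species, sex and disease model carry a categorical value;
#' all other items are binary detections.
#'
#' @return Tibble with columns `item_id`, `domain`, `scope`, `value_mode`.
#' @export
item_schema <- function() {
  tibble(
    item_id = c("species", "sex", "disease_model", "outcome_histology",
                "outcome_behaviour", "outcome_imaging", "randomization",
                "blinding", "animal_welfare", "conflict_of_interest",
                "sample_size_calculation", "arrive_guidelines",
                "data_availability"),
    domain = c(rep("experimental_parameter", 6), rep("risk_of_bias", 7)),
    scope = c(rep("methods", 6), rep("methods", 3), rep("full_minus_refs", 4)),
    value_mode = c(rep("categorical", 3), rep("binary", 10))
  )
}

categorical_items <- function() {
  item_schema()$item_id[item_schema()$value_mode == "categorical"]
}

#' Read and compile an item library from YAML
#'
#' The config is a YAML list with one entry per item: `item_id`, `patterns`
#' (each with `pattern_id`, `pattern`, optional `category`), and optional
#' `negative_patterns` (regexes that suppress a hit when they match within
#' a +/-200-character window around it). Domain, scope and value mode come
#' from [item_schema()] and cannot be overridden: scoping is part of the
#' method, not the config.
#'
#' All 13 items must be present, pattern ids must be unique, and every
#' pattern must compile; violations raise a configuration error naming the
#' offender. All patterns are matched case-insensitively.
#'
#' @param path YAML library file.
#' @return An `item_library`: tibble with one row per item and list-columns
#'   `patterns` (tibble of pattern_id / pattern / category) and
#'   `negative_patterns` (character).
#' @export
compile_library <- function(path) {
  entries <- yaml::read_yaml(path)
  schema <- item_schema()
  ids <- purrr::map_chr(entries, function(e) e$item_id %||% NA_character_)
  if (anyNA(ids)) abort("library entry without item_id",
                        class = "vivomine_config_error")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate item_id in library: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "vivomine_config_error")
  }
  missing <- setdiff(schema$item_id, ids)
  if (length(missing) > 0) {
    abort(sprintf("library is missing items: %s",
                  paste(missing, collapse = ", ")),
          class = "vivomine_config_error")
  }
  unknown <- setdiff(ids, schema$item_id)
  if (length(unknown) > 0) {
    abort(sprintf("library has unknown items: %s",
                  paste(unknown, collapse = ", ")),
          class = "vivomine_config_error")
  }

  rows <- purrr::map(entries, function(e) {
    pats <- purrr::map(e$patterns, function(p) {
      check_pattern(e$item_id, p$pattern_id, p$pattern)
      tibble(pattern_id = p$pattern_id, pattern = p$pattern,
             category = p$category %||% NA_character_)
    })
    pats <- bind_rows(pats)
    if (nrow(pats) == 0) {
      abort(sprintf("item '%s' has no patterns", e$item_id),
            class = "vivomine_config_error")
    }
    if (anyDuplicated(pats$pattern_id)) {
      abort(sprintf("item '%s': duplicate pattern_id: %s", e$item_id,
                    paste(unique(pats$pattern_id[duplicated(pats$pattern_id)]),
                          collapse = ", ")),
            class = "vivomine_config_error")
    }
    neg <- as.character(unlist(e$negative_patterns %||% character(0)))
    for (np in neg) check_pattern(e$item_id, "<negative>", np)
    tibble(item_id = e$item_id,
           patterns = list(pats),
           negative_patterns = list(neg))
  })
  lib <- left_join(schema, bind_rows(rows), by = "item_id")
  structure(lib, class = c("item_library", class(lib)))
}

check_pattern <- function(item_id, pattern_id, pattern) {
  if (is.null(pattern) || !nzchar(pattern)) {
    abort(sprintf("item '%s', pattern '%s': empty pattern", item_id, pattern_id),
          class = "vivomine_config_error")
  }
  ok <- tryCatch({
    stringr::str_detect("", stringr::regex(pattern, ignore_case = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf("item '%s', pattern '%s' does not compile: %s",
                  item_id, pattern_id, pattern),
          class = "vivomine_config_error")
  }
  invisible(TRUE)
}

#' @rdname compile_library
#' @details `default_item_library()` loads the library shipped with the
#'   package (`inst/extdata/item_library.yaml`).
#' @export
default_item_library <- function() {
  compile_library(system.file("extdata", "item_library.yaml",
                              package = "vivomine", mustWork = TRUE))
}

#' @export
print.item_library <- function(x, ...) {
  cat(sprintf("<item_library> %d items, %d patterns\n", nrow(x),
              sum(purrr::map_int(x$patterns, nrow))))
  NextMethod()
}
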