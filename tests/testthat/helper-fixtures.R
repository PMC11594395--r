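# shared fixture builders; everything is generated in code at test time

# equal-prevalence profile: every item has both positive and negative
# documents, so sensitivity and specificity are both measurable
prevalence_half <- function() {
  stats::setNames(rep(0.5, 13), item_schema()$item_id)
}

corpus_texts <- function(corpus) {
  stats::setNames(corpus$docs$text, corpus$docs$doc_id)
}

# a minimal hand-built article with known content per section
tiny_article <- function(methods = "Mice were randomly allocated to treatment groups.",
                         discussion = "The authors declare no conflict of interest.",
                         references = "1. Doe J. A randomized trial in blinded mice. 2020.") {
  paste(
    "Abstract", "", "We summarize the study.", "",
    "Introduction", "", "Context sentences are given here.", "",
    "Methods", "", methods, "",
    "Results", "", "An effect was observed.", "",
    "Discussion", "", discussion, "",
    "References", "", references,
    sep = "\n")
}

lib_item <- function(lib, id) as.list(lib[lib$item_id == id, ])
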