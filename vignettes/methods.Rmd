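---
title: "Mining experimental parameters and risk-of-bias items: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining experimental parameters and risk-of-bias items: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vivomine)
```

## The extraction model

`vivomine` treats data extraction from a full-text publication as scoped
pattern matching. The model rests on three assumptions that hold well for
preclinical *in vivo* reports and are worth stating explicitly:

1. **Reporting is formulaic.** Statements like "animals were randomly
   allocated", "assessed by a blinded investigator" or "approved by the
   institutional animal care and use committee" come from a small phrase
   vocabulary per item, so a curated regular-expression bank per item can
   reach high sensitivity without any learned model.
2. **Structure carries meaning.** Where a phrase occurs matters: species,
   sex, model, outcome modalities, randomization, blinding and welfare
   compliance are methods-section facts, while conflict-of-interest,
   sample-size-calculation, ARRIVE and data-availability statements live
   anywhere in the body. Restricting each item to its scope is the main
   false-positive control — a citation titled "A randomized trial…" in the
   references must never count as randomization.
3. **Errors are reviewable.** Every detection records the pattern id,
   section and matched span, so a human reviewer can audit any decision.
   The intended deployment is surveying large reference libraries or
   replacing one of two human readers, not unsupervised extraction.

## The 13-item schema

Six experimental parameters (species, sex, disease model, and histology /
behaviour / imaging outcomes) and seven risk-of-bias items (randomization,
blinding, animal welfare, conflict of interest, sample-size calculation,
ARRIVE adherence, data availability). Species, sex and disease model are
categorical — the extracted value is the category of the earliest hit in
document order, a deterministic rule chosen because multi-species papers
are rare and any fixed tie-break beats an arbitrary one. All other items
are binary detections.

The schema, including each item's scope, is fixed in `item_schema()` and
cannot be overridden by a library file: scoping is part of the method, the
pattern vocabulary is configuration. The shipped library
(`inst/extdata/item_library.yaml`) is a curated reconstruction for
preclinical neuroscience (motor neuron disease and multiple sclerosis
vocabularies); adapting the tool to another field means writing a new
library file, not new code. Patterns are matched case-insensitively and
use word-boundary anchors so that short tokens ("rat", "ALS") cannot fire
inside longer words ("stratification").

## False-positive control: cleaning and negative patterns

Two complementary mechanisms suppress lexical collisions:

* **Cleaning rules** run once, globally, before sectioning: phrases such
  as "random primer" or "random hexamer" (molecular-biology reagents, not
  study design) are replaced by a space. Cleaning is idempotent and
  case-insensitive, and replacement-with-space preserves word boundaries
  around the excision.
* **Negative patterns** are per-item vetoes applied at match time: a hit
  is discarded when a negative pattern (e.g. "random-effects") matches
  within ±200 characters. The window is character-based because sentence
  segmentation on text reflowed from PDFs is unreliable; 200 characters
  approximates a sentence of context on either side.

## Text normalization and sectioning

PDF extraction and copy-paste text share the same hygiene pass: ligatures
(fi, fl, …) expanded, soft hyphens removed, line-break hyphenation
repaired ("randomi-\\nzation" → "randomization"), runs of whitespace
collapsed, and paragraph breaks (blank lines) preserved as single
newlines. Normalization is deliberately *not* idempotent — it reduces
paragraph breaks to single newlines — so the pipeline normalizes exactly
once; `segment_sections(..., normalize = FALSE)` exists for already
normalized input.

Headings are recognized only at line starts, case-insensitively, tolerant
of numbering prefixes and trailing punctuation, via a configurable synonym
table (`default_headings()`): "Materials and Methods", "Experimental
Procedures" and "Methods and Materials" all map to methods, "Results and
Discussion" to results, "Summary" to abstract. Leading untitled text is
treated as the abstract when no abstract heading exists, matching the
common layout where the abstract is unlabelled.

The references block is defined as the *terminal* block: the earliest
references-type heading ("References", "Bibliography", "Literature
Cited") with no later non-references heading after it, running to the end
of text. This definition survives a "References" entry in a table of
contents and makes stripping idempotent; back-matter after the reference
list (appendices with their own recognized headings) would defeat it, a
known limitation.

When no methods heading is found, methods-scoped items fall back to the
full body minus references, and the document is flagged
(`methods_fallback_used`, manifest status `fallback_methods`) so
evaluations can stratify by it. The fallback trades specificity for
sensitivity, consistent with the sensitivity-weighted adequacy thresholds
below; it can be disabled (`allow_fallback = FALSE`).

## Evaluation conventions

Per item, each aligned (document, item) pair falls into exactly one
confusion-matrix cell; pairs with an NA gold label are excluded pairwise.
The five metrics are sensitivity TP/(TP+FN), specificity TN/(TN+FP),
precision TP/(TP+FP), accuracy (TP+TN)/total (percentages) and
F1 = 2TP/(2TP+FP+FN) (a fraction). Three conventions matter:

* **NA, never 0.** A zero denominator yields NA — e.g. specificity on a
  corpus where every paper reports species. NA propagates to display as
  "NA".
* **Thresholds are inclusive and pass on NA.** The SLIM adequacy bar is
  sensitivity ≥ 85% and specificity ≥ 80%; exactly 85/80 passes, 84.9
  fails. An NA metric passes its own threshold, and such items are flagged
  (`threshold_na`, `pass_on_na` in the display table) so readers can see
  which passes rest on an undefined denominator rather than a measured
  one.
* **Wrong categorical value is a miss.** In `value_match` mode a detected
  species with the wrong value scores FN (the correct value was missed),
  not FN+FP: row totals stay equal to the number of scored documents.
  Detection mode is the default because published performance figures for
  tools of this kind do not consistently distinguish the two readings.

Display rounding is half-up to integer percent and two decimals for F1;
full precision is retained internally and in `tidy()` output. Reporting
prevalence uses the same machinery (share of gold-positive documents),
with one display quirk: values above 99% but below 100% render as
">99%" so that a single non-reporting paper in a large corpus is not
rounded away. Interrater agreement is raw percent agreement — the share
of identical labels — reported per item and pooled; chance-corrected
coefficients are deliberately out of scope.

## The synthetic-corpus generator

The generator exists because full-text corpora of published PDFs cannot
be redistributed: every end-to-end property of the pipeline is
demonstrated on mock IMRaD articles whose ground truth is known by
construction.

**What it emulates.** Abstract / introduction / methods / results /
discussion / references blocks under five heading dialects and three text
layouts (paragraph, sentence-per-line, hard-wrapped at 80 columns), plus
an uncompressed single-column PDF rendering; per-item positive statements
drawn from template banks and planted in the item's policy section;
reference blocks always seeded with decoy citations loaded with item
vocabulary ("randomized controlled trial…", "Power analysis and sample
size calculation…") that must never produce hits; optional distractor
phrases targeted by the cleaning rules; abstract echoes of species /
model / outcome statements at 97% and of sex at 3%, mirroring how rarely
animal sex reaches abstracts (reported frequencies of 0–5% versus
95–100% for models and outcomes).

**Defaults are the study conditions.** The default per-item prevalence
profile (`default_prevalence()`) mirrors a training corpus of 45 motor
neuron disease publications — species and model near-universal, sex 87%,
outcome imaging 2%, risk-of-bias items sparse (sample-size calculation
27%, ARRIVE 29%) — and the default corpus size is 45. Prevalence is
quota-sampled: exactly `round(n × p)` documents are gold-positive per
item, so corpus descriptives are exact rather than binomially noisy.

**Error injection is quota-based too.** A miss rate m replaces exactly
`round(m × n_positives)` planted statements with paraphrases the library
intentionally misses ("allocation decided by coin toss"); a false-alarm
rate f plants, in exactly `round(f × n_negatives)` gold-negative
documents, sentences that match the library but are semantically negative
and survive cleaning ("a randomization test of 1000 permutations"). Gold
labels always follow the planted content, not its detectability — that is
what lets the suite measure true misses and false alarms. Quota injection
was chosen over per-document coin flips so that a calibration corpus
realizes the injected rates exactly (up to rounding): the calibration
test then measures the extractor, not the generator's sampling noise.

**Determinism.** One root seed drives quota assignment and a per-document
substream seed; the same spec and seed reproduce the corpus byte for
byte, including written files.

**What it does not emulate.** Multi-column reflow artifacts, tables,
figure legends, scanned/OCR text, non-English text, and real journal
typography. Passing the synthetic suite therefore demonstrates that the
pipeline's logic is correct — scoping, cleaning, metric arithmetic,
calibrated recovery — but not that the shipped pattern library reaches
any particular performance on real corpora; that requires a gold-standard
evaluation on the target literature, which the evaluation module supports
but the package cannot ship.

## Validation problem sizes

The test suite and the acceptance script use: 1,000 random confusion
matrices against an arithmetic oracle; a 200-document clean corpus for
exact 100/100 recovery; a 500-document corpus with a 15% miss and 10%
false-alarm rate for calibrated recovery within two binomial standard
errors; 60 documents saturated with cleaning-rule distractors; and the
full 5-dialect × 3-layout sectioning matrix. Calibration and
clean-recovery corpora use a flat 50% prevalence profile so every item has
both gold-positive and gold-negative documents — otherwise sensitivity or
specificity would be structurally NA and "exact recovery" unmeasurable.

## PDF support

No general PDF parser is included. The package writes and reads a simple
uncompressed single-column PDF subset (Helvetica, one text block per
page), which is exactly what the generator emits; the reader refuses
encrypted files by name and treats empty extraction as an ingestion error
so image-only files are skipped with a logged status rather than silently
extracted as empty. Real journal PDFs should be converted to plain text
with an external tool; plain-text ingestion is first-class throughout.

## Known limitations

* The shipped library is a functional reconstruction for preclinical
  neuroscience; other fields need their own library file and a new
  gold-standard validation.
* Number-of-animals extraction is out of scope: group sizes are reported
  too heterogeneously (tables, figure legends, per-arm counts) for
  pattern matching to be reliable.
* Headings merged into their paragraph (no blank line after the heading
  in the source) are not recognized after normalization.
* The methods fallback can inflate false positives on documents with
  unrecognized methods headings; the per-document flag exists precisely
  so such documents can be reviewed or excluded.
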