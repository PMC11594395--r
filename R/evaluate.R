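# Scoring extraction output against a gold standard: per-item confusion
# matrices, the five performance metrics (sensitivity, specificity,
# precision, accuracy, F1), reporting prevalence and interrater agreement.
#
# NA convention, used throughout: a metric whose denominator is zero is
# NA — e.g. specificity is undefined on a corpus with no item-negative
# papers — and NA propagates to display as "NA", never as 0.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read gold-standard annotations
#'
#' One row per document: `doc_id`, one column per item with labels 1 / 0 /
#' NA (NA marks "not assessed" and is excluded pairwise from metrics),
#' optional `<item>_value` columns carrying the categorical value for
#' species / sex / disease model, optional `annotator_id`.
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_gold <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(item_schema()$item_id, names(g))
  if (length(missing) > 0) {
    abort(sprintf("gold file lacks item columns: %s",
                  paste(missing, collapse = ", ")),
          class = "vivomine_config_error")
  }
  g
}

#' Per-item confusion matrices
#'
#' Scores each aligned (document, item) pair into exactly one cell of that
#' item's confusion matrix. In `detection` mode any machine detection of a
#' gold-positive item is a TP. In `value_match` mode, a categorical item
#' additionally requires the extracted value to equal the gold value
#' (column `<item>_value` in the gold table); a detection with the wrong
#' value counts as FN — the correct value was missed — so row totals stay
#' equal to the number of scored documents.
#'
#' @param extractions Extraction table from [extract_corpus()].
#' @param gold Gold tibble ([read_gold()]); must cover every extracted
#'   `doc_id`.
#' @param mode `"detection"` (default) or `"value_match"`.
#' @return Tibble: `item_id`, `tp`, `fp`, `tn`, `fn`, `n_scored` (pairs
#'   with a defined gold label).
#' @export
confusion <- function(extractions, gold, mode = c("detection", "value_match")) {
  mode <- match.arg(mode)
  missing <- setdiff(extractions$doc_id, gold$doc_id)
  if (length(missing) > 0) {
    abort(sprintf("documents missing from gold standard: %s",
                  paste(missing, collapse = ", ")),
          class = "vivomine_eval_error")
  }
  g <- gold[match(extractions$doc_id, gold$doc_id), ]
  purrr::map_dfr(item_schema()$item_id, function(item) {
    pred <- as.logical(extractions[[item]])
    truth <- as.integer(g[[item]]) == 1L
    ok <- !is.na(truth) & !is.na(pred)
    pred <- pred[ok]; truth <- truth[ok]
    if (mode == "value_match" && item %in% categorical_items()) {
      vcol <- paste0(item, "_value")
      if (!is.null(gold[[vcol]])) {
        gv <- as.character(g[[vcol]])[ok]
        ev <- as.character(extractions[[vcol]])[ok]
        # a detection with the wrong value did not extract the datum
        pred <- pred & (!truth | (!is.na(ev) & !is.na(gv) & ev == gv))
      }
    }
    tibble(item_id = item,
           tp = sum(pred & truth), fp = sum(pred & !truth),
           tn = sum(!pred & !truth), fn = sum(!pred & truth),
           n_scored = sum(ok))
  })
}

#' Performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
#' and accuracy (TP+TN)/total as percentages; F1 = 2TP/(2TP+FP+FN) as a
#' fraction. Any metric with a zero denominator is NA. `threshold_pass`
#' applies the SLIM adequacy bar — sensitivity >= 85 and specificity >= 80,
#' both inclusive — with an NA metric passing its own threshold (flagged
#' via `threshold_na`).
#'
#' @param cm Tibble with columns `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion()]); extra columns are carried through.
#' @param sens_threshold,spec_threshold Adequacy thresholds in percent.
#' @return Input tibble plus `sensitivity`, `specificity`, `precision`,
#'   `accuracy` (percent, full precision), `f1` (fraction),
#'   `threshold_pass`, `threshold_na`.
#' @export
compute_metrics <- function(cm, sens_threshold = 85, spec_threshold = 80) {
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  out <- mutate(as_tibble(cm),
    sensitivity = rate(.data$tp, .data$tp + .data$fn),
    specificity = rate(.data$tn, .data$tn + .data$fp),
    precision = rate(.data$tp, .data$tp + .data$fp),
    accuracy = rate(.data$tp + .data$tn,
                    .data$tp + .data$tn + .data$fp + .data$fn),
    f1 = ifelse(2 * .data$tp + .data$fp + .data$fn > 0,
                2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn),
                NA_real_))
  mutate(out,
    threshold_na = is.na(.data$sensitivity) | is.na(.data$specificity),
    threshold_pass =
      (is.na(.data$sensitivity) | .data$sensitivity >= sens_threshold) &
      (is.na(.data$specificity) | .data$specificity >= spec_threshold))
}

#' Evaluate an extraction table against a gold standard
#'
#' Convenience wrapper: [confusion()] then [compute_metrics()], returned
#' as an evaluation object with [tidy()], [glance()] and [autoplot()]
#' methods.
#'
#' @inheritParams confusion
#' @param sens_threshold,spec_threshold See [compute_metrics()].
#' @return A `vivomine_eval` object.
#' @export
evaluate_extractions <- function(extractions, gold,
                                 mode = c("detection", "value_match"),
                                 sens_threshold = 85, spec_threshold = 80) {
  mode <- match.arg(mode)
  cm <- confusion(extractions, gold, mode)
  structure(
    list(metrics = compute_metrics(cm, sens_threshold, spec_threshold),
         mode = mode, n_docs = nrow(extractions),
         sens_threshold = sens_threshold, spec_threshold = spec_threshold),
    class = "vivomine_eval")
}

#' @export
print.vivomine_eval <- function(x, ...) {
  cat(sprintf("<vivomine_eval> %d documents, mode = %s\n", x$n_docs, x$mode))
  print(threshold_report(x))
  invisible(x)
}

#' @rdname evaluate_extractions
#' @param x,object A `vivomine_eval`.
#' @param ... Unused.
#' @method tidy vivomine_eval
#' @export
tidy.vivomine_eval <- function(x, ...) x$metrics

#' @rdname evaluate_extractions
#' @method glance vivomine_eval
#' @export
glance.vivomine_eval <- function(x, ...) {
  m <- x$metrics
  tibble(n_docs = x$n_docs, n_items = nrow(m),
         n_pass = sum(m$threshold_pass),
         median_sensitivity = stats::median(m$sensitivity, na.rm = TRUE),
         median_specificity = stats::median(m$specificity, na.rm = TRUE),
         median_f1 = stats::median(m$f1, na.rm = TRUE),
         mode = x$mode)
}

#' Formatted threshold report
#'
#' Display table in the house style of extraction-performance summaries:
#' integer percentages (half-up), F1 to two decimals, `NA` for undefined
#' cells, and metrics meeting their adequacy threshold (sensitivity >= 85,
#' specificity >= 80, inclusive) marked in bold (`**96**`).
#'
#' @param x A `vivomine_eval` or a metrics tibble from [compute_metrics()].
#' @return Tibble of display strings plus the `pass` flag.
#' @export
threshold_report <- function(x) {
  m <- if (inherits(x, "vivomine_eval")) x$metrics else x
  sens_thr <- if (inherits(x, "vivomine_eval")) x$sens_threshold else 85
  spec_thr <- if (inherits(x, "vivomine_eval")) x$spec_threshold else 80
  pct <- function(v, thr = NULL) {
    s <- ifelse(is.na(v), "NA", sprintf("%d", round_half_up(v)))
    if (!is.null(thr)) s <- ifelse(!is.na(v) & v >= thr,
                                   paste0("**", s, "**"), s)
    s
  }
  tibble(
    item_id = m$item_id,
    specificity = pct(m$specificity, spec_thr),
    sensitivity = pct(m$sensitivity, sens_thr),
    precision = pct(m$precision),
    accuracy = pct(m$accuracy),
    f1 = ifelse(is.na(m$f1), "NA", sprintf("%.2f", round_half_up(m$f1, 2))),
    pass = m$threshold_pass,
    pass_on_na = m$threshold_na & m$threshold_pass
  )
}

#' Reporting prevalence per item
#'
#' Share of documents whose gold label marks the item as reported, as a
#' percentage. The display string renders values above 99% but below 100%
#' as ">99%" and rounds the rest half-up to integer percent.
#'
#' @param gold Gold tibble ([read_gold()]).
#' @return Tibble: `item_id`, `domain`, `n` (documents with a defined
#'   label), `prevalence` (percent, full precision), `display`.
#' @seealso [prevalence_medians()] for the per-domain medians.
#' @export
reporting_prevalence <- function(gold) {
  stopifnot(nrow(gold) >= 1)
  purrr::map_dfr(seq_len(nrow(item_schema())), function(i) {
    item <- item_schema()$item_id[i]
    lab <- as.integer(gold[[item]])
    ok <- !is.na(lab)
    p <- if (any(ok)) 100 * mean(lab[ok] == 1L) else NA_real_
    tibble(item_id = item, domain = item_schema()$domain[i],
           n = sum(ok), prevalence = p,
           display = format_prevalence(p))
  })
}

format_prevalence <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "NA",
    p > 99 & p < 100 ~ ">99%",
    TRUE ~ sprintf("%d%%", round_half_up(p))
  )
}

#' @rdname reporting_prevalence
#' @details `prevalence_medians()` gives the median prevalence over the
#'   experimental-parameter items and over the risk-of-bias items
#'   separately.
#' @export
prevalence_medians <- function(gold) {
  prev <- reporting_prevalence(gold)
  summarise(group_by(prev, .data$domain),
            median_prevalence = stats::median(.data$prevalence, na.rm = TRUE),
            .groups = "drop")
}

#' Interrater agreement
#'
#' Raw percent agreement between two annotators: the share of (document,
#' item) pairs with identical binary labels. Pairs where either label is
#' NA are excluded. Returned per item, with a final `pooled` row over all
#' pairs.
#'
#' @param gold_a,gold_b Gold tibbles covering the same documents.
#' @return Tibble: `item_id`, `n_pairs`, `agreement` (percent).
#' @export
interrater_agreement <- function(gold_a, gold_b) {
  if (!setequal(gold_a$doc_id, gold_b$doc_id)) {
    abort("annotator document sets differ", class = "vivomine_eval_error")
  }
  b <- gold_b[match(gold_a$doc_id, gold_b$doc_id), ]
  per_item <- purrr::map_dfr(item_schema()$item_id, function(item) {
    la <- as.integer(gold_a[[item]])
    lb <- as.integer(b[[item]])
    ok <- !is.na(la) & !is.na(lb)
    tibble(item_id = item, n_pairs = sum(ok),
           agreement = if (any(ok)) 100 * mean(la[ok] == lb[ok]) else NA_real_)
  })
  pooled <- summarise(per_item,
    item_id = "pooled",
    agreement = ifelse(sum(.data$n_pairs) > 0,
                       sum(.data$agreement * .data$n_pairs, na.rm = TRUE) /
                         sum(.data$n_pairs[!is.na(.data$agreement)]),
                       NA_real_),
    n_pairs = sum(.data$n_pairs))
  bind_rows(per_item, pooled[, c("item_id", "n_pairs", "agreement")])
}
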