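# independent scoring oracle: plain loop over (doc, item) pairs
loop_confusion <- function(pred_tab, gold_tab, item) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred_tab))) {
    gi <- which(gold_tab$doc_id == pred_tab$doc_id[i])
    truth <- gold_tab[[item]][gi]
    if (is.na(truth)) next
    p <- isTRUE(pred_tab[[item]][i])
    if (p && truth == 1) tp <- tp + 1L
    if (p && truth == 0) fp <- fp + 1L
    if (!p && truth == 0) tn <- tn + 1L
    if (!p && truth == 1) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

random_tables <- function(n, seed, na_rate = 0) {
  set.seed(seed)
  items <- item_schema()$item_id
  ids <- sprintf("D%03d", seq_len(n))
  pred <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(lapply(items, function(i) sample(c(TRUE, FALSE), n, TRUE)),
                    items)))
  gold <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(lapply(items, function(i)
      sample(c(1L, 0L, NA), n, TRUE,
             prob = c((1 - na_rate) / 2, (1 - na_rate) / 2, na_rate))),
      items)))
  list(pred = pred, gold = gold)
}

test_that("confusion matches a brute-force loop oracle on random corpora", {
  tabs <- random_tables(100, seed = 31, na_rate = 0.1)
  cm <- confusion(tabs$pred, tabs$gold)
  for (item in item_schema()$item_id) {
    oracle <- loop_confusion(tabs$pred, tabs$gold, item)
    row <- cm[cm$item_id == item, ]
    expect_equal(c(tp = row$tp, fp = row$fp, tn = row$tn, fn = row$fn),
                 oracle, label = item)
    # every scored pair lands in exactly one cell
    expect_equal(row$tp + row$fp + row$tn + row$fn, row$n_scored)
  }
})

test_that("degenerate corpora fill the expected cells", {
  items <- item_schema()$item_id
  ids <- sprintf("D%02d", 1:10)
  all_pos_pred <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(rep(list(rep(TRUE, 10)), 13), items)))
  all_pos_gold <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(rep(list(rep(1L, 10)), 13), items)))
  cm <- confusion(all_pos_pred, all_pos_gold)
  expect_true(all(cm$tp == 10 & cm$fp == 0 & cm$tn == 0 & cm$fn == 0))

  all_neg_pred <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(rep(list(rep(FALSE, 10)), 13), items)))
  cm2 <- confusion(all_neg_pred, all_pos_gold)
  expect_true(all(cm2$fn == 10 & cm2$tp == 0))

  # extraction doc missing from gold is an error listing the id
  expect_error(confusion(all_pos_pred, all_pos_gold[-1, ]), "D01",
               class = "vivomine_eval_error")
})

test_that("value_match scores a wrong categorical value as a miss", {
  ids <- c("a", "b", "c")
  items <- item_schema()$item_id
  base <- stats::setNames(rep(list(rep(FALSE, 3)), 13), items)
  pred <- tibble::as_tibble(c(list(doc_id = ids), base))
  pred$species <- c(TRUE, TRUE, FALSE)
  pred$species_value <- c("mouse", "rat", NA)
  gold <- tibble::as_tibble(c(list(doc_id = ids),
    stats::setNames(rep(list(rep(0L, 3)), 13), items)))
  gold$species <- c(1L, 1L, 1L)
  gold$species_value <- c("mouse", "mouse", "mouse")

  det <- confusion(pred, gold, mode = "detection")
  expect_equal(det$tp[det$item_id == "species"], 2)
  expect_equal(det$fn[det$item_id == "species"], 1)

  vm <- confusion(pred, gold, mode = "value_match")
  row <- vm[vm$item_id == "species", ]
  expect_equal(row$tp, 1)      # right value
  expect_equal(row$fn, 2)      # wrong value counts as a miss, not FP
  expect_equal(row$fp, 0)
  expect_equal(row$tp + row$fp + row$tn + row$fn, 3)
})

test_that("metric formulas match hand-computed expectations incl. NA cells", {
  m1 <- compute_metrics(tibble::tibble(item_id = "x", tp = 10, fp = 0,
                                       tn = 0, fn = 0))
  expect_equal(m1$sensitivity, 100)
  expect_true(is.na(m1$specificity))
  expect_equal(m1$accuracy, 100)
  expect_equal(m1$f1, 1.0)

  m2 <- compute_metrics(tibble::tibble(item_id = "x", tp = 1, fp = 1,
                                       tn = 1, fn = 1))
  expect_equal(unlist(m2[, c("sensitivity", "specificity", "precision",
                             "accuracy")]),
               c(sensitivity = 50, specificity = 50, precision = 50,
                 accuracy = 50))
  expect_equal(m2$f1, 0.5)

  m3 <- compute_metrics(tibble::tibble(item_id = "x", tp = 46, fp = 0,
                                       tn = 0, fn = 2))
  expect_equal(m3$sensitivity, 100 * 46 / 48)
  expect_equal(round(m3$sensitivity), 96)
  expect_equal(round(m3$f1, 2), 0.98)

  m0 <- compute_metrics(tibble::tibble(item_id = "x", tp = 0, fp = 0,
                                       tn = 0, fn = 0))
  expect_true(all(is.na(unlist(
    m0[, c("sensitivity", "specificity", "precision", "accuracy", "f1")]))))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(41)
  for (i in 1:200) {
    cm <- tibble::tibble(item_id = "x", tp = sample(0:30, 1),
                         fp = sample(0:30, 1), tn = sample(0:30, 1),
                         fn = sample(0:30, 1))
    m <- compute_metrics(cm)
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        (m$precision + m$sensitivity) > 0) {
      hm <- 2 * (m$precision / 100) * (m$sensitivity / 100) /
        (m$precision / 100 + m$sensitivity / 100)
      expect_equal(m$f1, hm, tolerance = 1e-12)
    }
    # accuracy * total = TP + TN
    if (!is.na(m$accuracy)) {
      expect_equal(m$accuracy / 100 * (cm$tp + cm$fp + cm$tn + cm$fn),
                   cm$tp + cm$tn, tolerance = 1e-12)
    }
  }
})

test_that("swapping machine and gold transposes the confusion matrix", {
  tabs <- random_tables(60, seed = 51)
  gold_as_pred <- tabs$gold
  for (it in item_schema()$item_id) {
    gold_as_pred[[it]] <- tabs$gold[[it]] == 1L
  }
  pred_as_gold <- tabs$pred
  for (it in item_schema()$item_id) {
    pred_as_gold[[it]] <- as.integer(tabs$pred[[it]])
  }
  a <- confusion(tabs$pred, tabs$gold)
  b <- confusion(gold_as_pred, pred_as_gold)
  expect_equal(a$tp, b$tp)
  expect_equal(a$tn, b$tn)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("metrics are invariant to document order", {
  tabs <- random_tables(40, seed = 61)
  perm <- sample(40)
  a <- confusion(tabs$pred, tabs$gold)
  b <- confusion(tabs$pred[perm, ], tabs$gold)
  expect_equal(a, b)
})

test_that("threshold flags use inclusive SLIM boundaries with pass-on-NA", {
  mk <- function(sens, spec) {
    # build integer counts achieving the target rates on 1000 docs
    tp <- round(sens * 10); fn <- 1000 - tp
    tn <- round(spec * 10); fp <- 1000 - tn
    compute_metrics(tibble::tibble(item_id = "x", tp = tp, fp = fp,
                                   tn = tn, fn = fn))
  }
  expect_true(mk(85, 80)$threshold_pass)
  expect_false(mk(84.9, 80)$threshold_pass)
  expect_false(mk(85, 79.9)$threshold_pass)
  expect_true(mk(100, 100)$threshold_pass)

  na_spec <- compute_metrics(tibble::tibble(item_id = "x", tp = 48, fp = 0,
                                            tn = 0, fn = 2))
  expect_true(na_spec$threshold_pass)
  expect_true(na_spec$threshold_na)

  rep <- threshold_report(compute_metrics(tibble::tibble(
    item_id = "species", tp = 46, fp = 0, tn = 0, fn = 2)))
  expect_equal(rep$sensitivity, "**96**")
  expect_equal(rep$specificity, "NA")
  expect_true(rep$pass)
})

test_that("reporting prevalence, display convention and domain medians", {
  items <- item_schema()$item_id
  n <- 45
  gold <- tibble::as_tibble(c(list(doc_id = sprintf("D%02d", 1:n)),
    stats::setNames(rep(list(rep(1L, n)), 13), items)))
  prev <- reporting_prevalence(gold)
  expect_true(all(prev$prevalence == 100))
  expect_equal(prev$display[prev$item_id == "species"], "100%")

  # >99% but <100% renders as ">99%"
  gold2 <- gold
  gold2$disease_model[1] <- 0L
  gold2 <- dplyr::bind_rows(gold2, gold2[rep(1, 200), ])
  gold2$doc_id <- sprintf("D%03d", seq_len(nrow(gold2)))
  gold2$disease_model <- c(0L, rep(1L, nrow(gold2) - 1))
  prev2 <- reporting_prevalence(gold2)
  expect_equal(prev2$display[prev2$item_id == "disease_model"], ">99%")

  # single document, item absent
  g1 <- gold[1, ]; g1$blinding <- 0L
  expect_equal(reporting_prevalence(g1)$prevalence[
    reporting_prevalence(g1)$item_id == "blinding"], 0)

  # domain medians: experimental items at known percentages
  set.seed(3)
  gold3 <- gold
  target <- c(species = 100, sex = 87, disease_model = 100,
              outcome_histology = 82, outcome_behaviour = 73,
              outcome_imaging = 2)
  # 50 docs make the target percentages exact
  gold3 <- tibble::as_tibble(c(list(doc_id = sprintf("E%03d", 1:100)),
    stats::setNames(rep(list(rep(1L, 100)), 13), items)))
  for (it in names(target)) {
    k <- target[[it]]
    gold3[[it]] <- c(rep(1L, k), rep(0L, 100 - k))
  }
  med <- prevalence_medians(gold3)
  expect_equal(
    med$median_prevalence[med$domain == "experimental_parameter"],
    stats::median(unname(target)))
  expect_equal(round(stats::median(unname(target))), 84)  # 84.5 rounds even
  expect_equal(vivomine:::round_half_up(stats::median(unname(target))), 85)
})

test_that("interrater agreement counts identical labels pairwise", {
  items <- item_schema()$item_id
  gold <- tibble::as_tibble(c(list(doc_id = sprintf("D%02d", 1:20)),
    stats::setNames(rep(list(rep(1L, 20)), 13), items)))
  same <- interrater_agreement(gold, gold)
  expect_true(all(same$agreement == 100))

  # one disagreement among 20 labels of one item
  g2 <- gold
  g2$blinding[1] <- 0L
  ag <- interrater_agreement(gold, g2)
  expect_equal(ag$agreement[ag$item_id == "blinding"], 95)

  # random disagreement pattern equals a loop count
  set.seed(71)
  g3 <- gold
  for (it in items) g3[[it]] <- sample(c(0L, 1L), 20, TRUE)
  ag3 <- interrater_agreement(gold, g3)
  for (it in items) {
    expect_equal(ag3$agreement[ag3$item_id == it],
                 100 * mean(gold[[it]] == g3[[it]]))
  }
  pooled <- ag3$agreement[ag3$item_id == "pooled"]
  manual <- 100 * mean(unlist(lapply(items, function(it)
    gold[[it]] == g3[[it]])))
  expect_equal(pooled, manual)

  expect_error(interrater_agreement(gold, g2[-1, ]),
               class = "vivomine_eval_error")
})

test_that("evaluation objects expose tidy, glance and autoplot", {
  corp <- generate_corpus(synth_spec(n_docs = 12, seed = 5,
                                     prevalence = prevalence_half()))
  ev <- evaluate_extractions(extract_corpus(corpus_texts(corp)), corp$gold)
  td <- generics::tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 13)
  gl <- generics::glance(ev)
  expect_equal(gl$n_docs, 12)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_prevalence(corp$gold), "ggplot")
})
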