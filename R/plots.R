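# ggplot2 displays for evaluation results and corpus descriptives.

#' Plot per-item performance against the adequacy thresholds
#'
#' Dot plot of sensitivity and specificity per item with the threshold
#' lines (sensitivity 85, specificity 80) overlaid; items failing either
#' threshold stand out below their line. NA metrics are omitted.
#'
#' @param object A `vivomine_eval` from [evaluate_extractions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vivomine_eval
#' @export
autoplot.vivomine_eval <- function(object, ...) {
  m <- tidyr::pivot_longer(
    object$metrics[, c("item_id", "sensitivity", "specificity")],
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value")
  m <- filter(m, !is.na(.data$value))
  thr <- tibble(metric = c("sensitivity", "specificity"),
                threshold = c(object$sens_threshold, object$spec_threshold))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$value, y = .data$item_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "percent", y = NULL,
                  title = "Extraction performance per item") +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot reporting prevalence per item
#'
#' Horizontal bars of gold-standard reporting prevalence, split by domain
#' (experimental parameters vs risk-of-bias items).
#'
#' @param gold Gold tibble ([read_gold()]).
#' @return A ggplot.
#' @export
plot_prevalence <- function(gold) {
  prev <- reporting_prevalence(gold)
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$prevalence,
                                     y = stats::reorder(.data$item_id,
                                                        .data$prevalence))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~domain, scales = "free_y") +
    ggplot2::labs(x = "reporting prevalence (%)", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
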