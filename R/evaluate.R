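#' Precision, recall and F1 for sequence labeling
#'
#' Two evaluation modes are provided. *Entity-level* scoring (the
#' BioCreative/NCBI convention) counts a predicted mention as a true
#' positive only when its span boundaries and category both match a gold
#' mention exactly; precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`
#' and F1 their harmonic mean. *Token-level per-label* scoring treats each
#' tag role (B, I, O) as a one-vs-rest token classification, which is the
#' mode under which an F1 for the "O" label is meaningful.
#'
#' Zero-denominator metrics are reported as 0 rather than an error, so
#' results aggregate robustly across runs. Values are kept as proportions
#' in `[0, 1]` at full precision; [format_pct()] renders them as
#' percentages rounded half-up to two decimals for display.
#'
#' @param gold,pred Span tibbles as returned by [corpus_spans()] (columns
#'   `sentence_id`, `start`, `end`, `category`).
#' @return `ner_confusion()` returns a one-row tibble with `tp`, `fp`,
#'   `fn`.
#' @export
ner_confusion <- function(gold, pred) {
  key <- function(s) paste(s$sentence_id, s$start, s$end, s$category,
                           sep = "\r")
  tp <- sum(key(pred) %in% key(gold))
  tibble::tibble(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

#' @rdname ner_confusion
#' @param tp,fp,fn Non-negative confusion counts (vectorized).
#' @return `ner_prf()` returns a tibble with `precision`, `recall`, `f1`
#'   as proportions.
#' @export
ner_prf <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  tibble::tibble(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall))
}

#' @rdname ner_confusion
#' @param precision,recall Precision and recall on any common scale
#'   (proportions or percentages).
#' @return `f1_score()` returns the harmonic mean on the same scale, 0
#'   when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' @rdname ner_confusion
#' @param data A corpus tibble carrying both a gold and a predicted label
#'   column.
#' @param gold_col,pred_col Names of the gold and predicted label columns.
#' @return `ner_evaluate()` returns a one-row tibble with `mode`,
#'   `precision`, `recall`, `f1`, `tp`, `fp`, `fn` (entity-level).
#' @export
ner_evaluate <- function(data, gold_col = "label", pred_col = ".pred") {
  g <- corpus_spans(data, gold_col)
  p <- corpus_spans(data, pred_col)
  counts <- ner_confusion(g, p)
  out <- dplyr::bind_cols(tibble::tibble(mode = "entity"),
                          ner_prf(counts$tp, counts$fp, counts$fn), counts)
  class(out) <- c("kgner_metrics", class(out))
  out
}

#' @rdname ner_confusion
#' @return `ner_label_metrics()` returns one row per tag role (B, I, O)
#'   with one-vs-rest token-level counts and metrics.
#' @export
ner_label_metrics <- function(data, gold_col = "label", pred_col = ".pred") {
  g <- data[[gold_col]]; p <- data[[pred_col]]
  if (length(g) != length(p) || anyNA(g) || anyNA(p)) {
    abort("gold and predicted label columns must align", class = "kgner_mismatch")
  }
  groles <- parse_bio(g)$role
  proles <- parse_bio(p)$role
  rows <- lapply(c("B", "I", "O"), function(r) {
    tp <- sum(groles == r & proles == r)
    fp <- sum(groles != r & proles == r)
    fn <- sum(groles == r & proles != r)
    dplyr::bind_cols(tibble::tibble(mode = "token-per-label", label = r),
                     ner_prf(tp, fp, fn),
                     tibble::tibble(tp = tp, fp = fp, fn = fn))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kgner_metrics", class(out))
  out
}

#' @rdname ner_confusion
#' @param reports A tibble stacking two or more metric reports of the same
#'   mode (e.g. `dplyr::bind_rows()` of [ner_evaluate()] outputs across
#'   seeds).
#' @return `aggregate_metrics()` returns a long tibble with `metric`,
#'   `mean` and `sd` (sample standard deviation, n - 1 denominator).
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 2)
  if ("mode" %in% names(reports) && length(unique(reports$mode)) > 1) {
    abort("cannot aggregate reports of mixed modes", class = "kgner_mixed_modes")
  }
  cols <- intersect(c("precision", "recall", "f1"), names(reports))
  tidyr::pivot_longer(reports[, cols], dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}

#' @rdname ner_confusion
#' @param x Proportions in `[0, 1]`.
#' @param digits Decimal places (rounded half-up).
#' @export
format_pct <- function(x, digits = 2) {
  scaled <- x * 100 * 10^digits
  sprintf(paste0("%.", digits, "f"), floor(scaled + 0.5) / 10^digits)
}

#' @rdname tidy.kgner_fit
#' @method autoplot kgner_metrics
#' @export
autoplot.kgner_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              dplyr::any_of(c("precision", "recall", "f1")),
                              names_to = "metric", values_to = "value")
  if (!"label" %in% names(long)) long$label <- "entity"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) format_pct(v, 0)) +
    ggplot2::labs(x = NULL, y = "percent", title = "NER metrics")
}
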