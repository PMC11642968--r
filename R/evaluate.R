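# Confusion matrices, per-class precision/recall/F1 reports, and model
# comparison tables.
#
# Conventions: a metric whose denominator is zero is reported as 0 (matching
# the published convention of 0.00 rows for classes the model never
# predicts); F1 is 0 whenever precision + recall is 0. Internal values are
# full precision; rounding (two decimals, half up) happens only at
# presentation time.

#' Confusion matrix
#'
#' Entry `(i, j)` counts observations of true class `i` predicted as class
#' `j`. Rows are true classes, columns predicted.
#'
#' @param true,pred Integer label vectors coded `1..K`, same length.
#' @param K Number of classes (default the max code observed).
#' @return A `perio_confusion` K x K integer matrix.
#' @export
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2), K = 2)
confusion <- function(true, pred, K = max(c(true, pred))) {
  true <- as.integer(true)
  pred <- as.integer(pred)
  if (length(true) != length(pred)) {
    abort("`true` and `pred` must have the same length")
  }
  if (any(c(true, pred) < 1) || any(c(true, pred) > K)) {
    abort(glue::glue("labels must be coded 1..{K}"))
  }
  cm <- table(factor(true, levels = seq_len(K)),
              factor(pred, levels = seq_len(K)))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(true = seq_len(K), pred = seq_len(K)))
  structure(cm, class = c("perio_confusion", class(cm)))
}

#' F1 from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, with the zero convention: 0 whenever
#' `P + R == 0`.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
#' @examples
#' f1_score(0.91, 0.75)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class metrics from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 per class (0 when the
#' denominator is 0), plus overall accuracy (trace / total). Values are kept
#' at full precision; see [present_metrics()] for table-style rounding.
#'
#' @param cm A `perio_confusion` matrix (or any square count matrix with true
#'   classes in rows).
#' @return A `perio_metrics` list: `by_class` tibble (`class`, `precision`,
#'   `recall`, `f1`, `support`) and scalar `accuracy`, `n`.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) == 0) {
    abort("`cm` must be a non-empty square matrix")
  }
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  structure(list(
    by_class = tibble::tibble(
      class = seq_len(K),
      precision = as.numeric(precision),
      recall = as.numeric(recall),
      f1 = f1_score(as.numeric(precision), as.numeric(recall)),
      support = as.integer(rowSums(cm))
    ),
    accuracy = sum(tp) / sum(cm),
    n = sum(cm),
    cm = cm
  ), class = "perio_metrics")
}

#' @export
print.perio_metrics <- function(x, ...) {
  cat("<perio_metrics> n =", x$n, " accuracy =", round(x$accuracy, 4), "\n")
  print(present_metrics(x))
  invisible(x)
}

#' @export
tidy.perio_metrics <- function(x, ...) x$by_class

#' @export
glance.perio_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_f1 = mean(x$by_class$f1),
    n = x$n,
    n_classes = nrow(x$by_class)
  )
}

#' Presentation rounding of a metric report
#'
#' Published clinical tables print two decimals, rounding half up, and some
#' round precision/recall before recomputing F1. `recompute_f1 = TRUE`
#' reproduces that style (F1 from rounded P/R); the default rounds the
#' full-precision F1.
#'
#' @param report A `perio_metrics` object.
#' @param digits Decimal places.
#' @param recompute_f1 Recompute F1 from the rounded precision/recall.
#' @param class_labels Optional display labels (e.g. `c("I","II","III","IV")`).
#' @return Tibble with rounded `precision`, `recall`, `f1` per class.
#' @export
present_metrics <- function(report, digits = 2, recompute_f1 = FALSE,
                            class_labels = NULL) {
  b <- report$by_class
  p <- round_half_up(b$precision, digits)
  r <- round_half_up(b$recall, digits)
  f <- if (recompute_f1) round_half_up(f1_score(p, r), digits)
       else round_half_up(b$f1, digits)
  tibble::tibble(
    class = class_labels %||% b$class,
    precision = p, recall = r, f1 = f, support = b$support
  )
}

#' Side-by-side comparison of two metric reports
#'
#' Emits the published layout: per class, one row per model with
#' precision/recall/F1, plus overall accuracies; `delta_*` columns carry
#' model A minus model B and are antisymmetric under swapping the reports.
#'
#' @param report_a,report_b `perio_metrics` objects over the same class set.
#' @param names Length-2 model display names.
#' @return A `perio_comparison` list: `table` (long layout) and `accuracy`
#'   tibble.
#' @export
compare_models <- function(report_a, report_b, names = c("model_a", "model_b")) {
  a <- report_a$by_class
  b <- report_b$by_class
  if (!identical(a$class, b$class)) {
    abort("reports cover different class sets")
  }
  long <- dplyr::bind_rows(
    dplyr::mutate(a, model = names[1]),
    dplyr::mutate(b, model = names[2])
  ) |>
    dplyr::arrange(.data$class, match(.data$model, names)) |>
    dplyr::select("class", "model", "precision", "recall", "f1", "support")
  delta <- tibble::tibble(
    class = a$class,
    delta_precision = a$precision - b$precision,
    delta_recall = a$recall - b$recall,
    delta_f1 = a$f1 - b$f1
  )
  structure(list(
    table = long,
    delta = delta,
    accuracy = tibble::tibble(model = names,
                              accuracy = c(report_a$accuracy, report_b$accuracy))
  ), class = "perio_comparison")
}

#' @export
print.perio_comparison <- function(x, ...) {
  cat("<perio_comparison>\n")
  print(dplyr::mutate(x$table, dplyr::across(c("precision", "recall", "f1"),
                                             ~ round_half_up(.x, 2))), n = Inf)
  print(x$accuracy)
  invisible(x)
}

#' Write a metrics report and confusion matrix to CSV
#'
#' @param report A `perio_metrics` object.
#' @param path_metrics,path_confusion Output CSV paths (confusion optional).
#' @return `path_metrics`, invisibly.
#' @export
write_metrics <- function(report, path_metrics, path_confusion = NULL) {
  out <- dplyr::bind_rows(
    dplyr::mutate(report$by_class, accuracy = report$accuracy)
  )
  readr::write_csv(out, path_metrics)
  if (!is.null(path_confusion)) {
    cm <- tibble::as_tibble(as.data.frame.matrix(unclass(report$cm)),
                            .name_repair = ~ paste0("pred_", seq_along(.x)))
    cm <- dplyr::bind_cols(tibble::tibble(true = seq_len(nrow(cm))), cm)
    readr::write_csv(cm, path_confusion)
  }
  invisible(path_metrics)
}
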