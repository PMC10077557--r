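#' Build a confusion matrix
#'
#' Counts with rows for the actual class and columns for the predicted
#' class, so `counts[i, j]` is the number of samples of class `i`
#' classified as class `j` and the diagonal holds the correct
#' classifications.
#'
#' @param actual,predicted Equal-length label vectors (factors, strings
#'   or integer class codes).
#' @param labels Optional vector fixing the class set and order; defaults
#'   to the factor levels or the sorted union of observed labels. Values
#'   outside `labels` are an error.
#' @return A `confusion_matrix` object (integer k x k matrix).
#' @examples
#' build_confusion(c(1, 1, 2), c(1, 2, 2), labels = 1:2)
#' @export
build_confusion <- function(actual, predicted, labels = NULL) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must be non-empty and of equal length.")
  }
  labels <- labels %||%
    (if (is.factor(actual)) levels(actual) else sort(unique(c(actual, predicted))))
  a <- factor(as.character(actual), levels = as.character(labels))
  p <- factor(as.character(predicted), levels = as.character(labels))
  if (anyNA(a) || anyNA(p)) {
    abort("labels outside the class set were found; check `labels`.")
  }
  counts <- unclass(table(actual = a, predicted = p))
  structure(matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' @describeIn build_confusion Long tibble of counts per
#'   (actual, predicted) cell.
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq")
}

#' @describeIn build_confusion Heatmap of the confusion counts.
#' @param object A `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  long <- tidy.confusion_matrix(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$predicted, .data$actual,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted", y = "actual") +
    ggplot2::theme_minimal()
}

#' Per-class classification metrics from a confusion matrix
#'
#' For each class `j`: recall is the percentage of actual class-`j`
#' samples predicted correctly (`100 N_jj / row_j`), precision the
#' percentage of class-`j` predictions that are correct
#' (`100 N_jj / col_j`), and the F-score their harmonic mean reported on
#' the 0-1 scale. Overall accuracy is `100 trace / total`. Classes with
#' an empty row or column get 0 for the undefined ratio, with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @return Tibble with columns `class`, `recall`, `precision`, `f_score`
#'   and `accuracy` (percentages except `f_score`; `accuracy` repeats the
#'   overall value on every row).
#' @examples
#' cm <- build_confusion(rep(1:2, each = 5), c(rep(1, 5), 2, 2, 2, 1, 1))
#' class_metrics(cm)
#' @export
class_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) abort("`cm` must be a confusion_matrix.")
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0L) abort("confusion matrix is empty (all-zero counts).")
  correct <- diag(counts)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  if (any(row_tot == 0L) || any(col_tot == 0L)) {
    warn("some classes have no actual or no predicted samples; reporting 0 for the undefined ratios.")
  }
  recall <- ifelse(row_tot > 0, correct / row_tot, 0)
  precision <- ifelse(col_tot > 0, correct / col_tot, 0)
  f_score <- ifelse(recall + precision > 0,
                    2 * recall * precision / (recall + precision), 0)
  tibble::tibble(
    class = rownames(counts),
    recall = unname(100 * recall),
    precision = unname(100 * precision),
    f_score = unname(f_score),
    accuracy = 100 * sum(correct) / total
  )
}

#' Regression-style prediction metrics
#'
#' Root mean square error of prediction
#' `RMSEP = sqrt(sum((y_act - y_pred)^2) / n)`, relative error of
#' prediction `REP = 100 RMSEP / mean(y_act)`, and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`. For classification models
#' these are conventionally computed on the integer class codes.
#'
#' @param actual,predicted Equal-length numeric vectors; `actual` must
#'   have non-zero variance (for R^2) and non-zero mean (for REP).
#' @return One-row tibble with `rmsep`, `rep_percent` and `r_squared`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 3, 4))
#' @export
regression_metrics <- function(actual, predicted) {
  if (!is.numeric(actual) || !is.numeric(predicted) ||
      length(actual) == 0L || length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must be equal-length non-empty numeric vectors.")
  }
  y_bar <- mean(actual)
  ss_tot <- sum((actual - y_bar)^2)
  if (ss_tot == 0) abort("`actual` has zero variance; R^2 is undefined.")
  if (y_bar == 0) abort("`actual` has zero mean; REP is undefined.")
  ss_res <- sum((actual - predicted)^2)
  rmsep <- sqrt(ss_res / length(actual))
  tibble::tibble(
    rmsep = rmsep,
    rep_percent = 100 * rmsep / y_bar,
    r_squared = 1 - ss_res / ss_tot
  )
}
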