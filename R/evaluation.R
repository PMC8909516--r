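#' Confusion matrix with rows = predicted, columns = reference
#'
#' @param y_true Reference labels, integers in `0..k-1` (or values of
#'   `class_names` when given).
#' @param y_pred Predicted labels, same coding.
#' @param k Number of classes.
#' @param class_names Optional class names (length `k`).
#' @return An object of class `confusion_matrix`: a `k x k` integer count
#'   matrix, `counts[p, r] = #{i : pred = p, ref = r}`.
#' @export
confusion <- function(y_true, y_pred, k, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stopf("confusion: label vectors differ in length (%d vs %d)",
          length(y_true), length(y_pred))
  if (length(y_true) == 0L)
    stopf("confusion: empty label vectors")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= k) || any(y_pred < 0L | y_pred >= k))
    stopf("confusion: labels outside 0..%d", k - 1L)
  counts <- matrix(tabulate(y_pred * k + y_true + 1L, nbins = k * k),
                   k, k, byrow = TRUE)
  as_confusion(counts, class_names)
}

#' Wrap a count matrix as a confusion matrix
#'
#' Accepts an already-tabulated `k x k` count table (rows = predicted,
#' columns = reference), e.g. a published validation table.
#' @param counts Square nonnegative integer matrix.
#' @param class_names Optional class names.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stopf("as_confusion: count matrix must be square")
  if (any(counts < 0) || sum(counts) <= 0)
    stopf("as_confusion: counts must be nonnegative with positive total")
  if (!is.null(class_names)) {
    stopifnot(length(class_names) == nrow(counts))
    dimnames(counts) <- list(predicted = class_names, reference = class_names)
  } else {
    dimnames(counts) <- list(predicted = rownames(counts),
                             reference = colnames(counts))
  }
  structure(counts, class = c("confusion_matrix", "matrix"))
}

# One-vs-rest marginal counts for class i (1-based row/col index).
ovr_counts <- function(cm, i) {
  n <- sum(cm)
  tp <- cm[i, i]
  fp <- sum(cm[i, ]) - tp      # predicted i, reference elsewhere
  fn <- sum(cm[, i]) - tp      # reference i, predicted elsewhere
  tn <- n - tp - fp - fn
  list(tp = tp, tn = tn, fp = fp, fn = fn, n = n)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class accuracy, precision, recall and F1
#'
#' One-vs-rest for class `i`: `accuracy = (TP + TN)/n`,
#' `precision = TP/(TP + FP)`, `recall = TP/(TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)` (the harmonic mean).
#' Undefined ratios (0/0) are reported as `NA`, never as 0.
#'
#' @param cm A `confusion_matrix`.
#' @param i Class index, 1-based (row/column position).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(cm, i) {
  if (i < 1 || i > nrow(cm))
    stopf("class_metrics: class index %d outside 1..%d", i, nrow(cm))
  m <- ovr_counts(cm, i)
  precision <- safe_ratio(m$tp, m$tp + m$fp)
  recall <- safe_ratio(m$tp, m$tp + m$fn)
  c(accuracy = (m$tp + m$tn) / m$n,
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall))
}

#' Harmonic-mean F1 from precision and recall
#'
#' `F1 = 2 p r / (p + r)`; `NA` when either input is `NA` or both are zero.
#' @param precision,recall Values in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Overall accuracy: trace over total
#' @param cm A `confusion_matrix`.
#' @export
overall_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' User's and producer's accuracy per class
#'
#' User's accuracy of class `i` is the row-wise precision
#' `counts[i, i] / rowSums[i]` (how often a map label is right); producer's
#' accuracy is the column-wise recall `counts[i, i] / colSums[i]` (how often a
#' reference member is found). Empty rows/columns yield `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @return Data frame with one row per class: `users`, `producers`.
#' @export
users_producers <- function(cm) {
  k <- nrow(cm)
  users <- vapply(seq_len(k), function(i) safe_ratio(cm[i, i], sum(cm[i, ])),
                  numeric(1))
  producers <- vapply(seq_len(k), function(i) safe_ratio(cm[i, i], sum(cm[, i])),
                      numeric(1))
  data.frame(class = rownames(cm) %||% as.character(seq_len(k) - 1L),
             users = users, producers = producers)
}

#' Cohen's Kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o = trace/n`
#' and chance agreement `p_e = sum_i row_i * col_i / n^2`. In the degenerate
#' single-class case (`p_e = 1`), returns 1 when agreement is also perfect.
#'
#' @param cm A `confusion_matrix`.
#' @export
kappa_coef <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Full accuracy report in validation-table layout
#'
#' Combines the confusion counts with user's/producer's accuracies per class,
#' per-class accuracy/precision/recall/F1, overall accuracy and Cohen's Kappa.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(cm) {
  k <- nrow(cm)
  per_class <- t(vapply(seq_len(k), function(i) class_metrics(cm, i),
                        numeric(4)))
  up <- users_producers(cm)
  structure(list(cm = cm,
                 per_class = cbind(up, as.data.frame(per_class)),
                 overall_accuracy = overall_accuracy(cm),
                 kappa = kappa_coef(cm)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cm <- x$cm
  k <- nrow(cm)
  pct <- function(v) ifelse(is.na(v), "-", sprintf(paste0("%.", digits, "f%%"),
                                                   100 * v))
  tab <- cbind(as.data.frame(unclass(cm)),
               Total = rowSums(cm),
               `User's Accuracy` = pct(x$per_class$users))
  cat("Confusion matrix (rows = classified, columns = reference):\n")
  print(tab)
  cat("Producer's Accuracy:", paste(pct(x$per_class$producers),
                                    collapse = "  "), "\n")
  cat(sprintf("Overall Accuracy %s   Kappa %s\n",
              pct(x$overall_accuracy), pct(x$kappa)))
  cat("\nPer-class metrics:\n")
  pc <- x$per_class
  pc[c("users", "producers", "accuracy", "precision", "recall", "f1")] <-
    lapply(pc[c("users", "producers", "accuracy", "precision", "recall",
                "f1")], function(v) round(100 * v, digits))
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Write a metric report as delimited text
#'
#' @param report A `metric_report`.
#' @param path Output file (CSV).
#' @export
write_metric_report <- function(report, path) {
  pc <- report$per_class
  pc$overall_accuracy <- report$overall_accuracy
  pc$kappa <- report$kappa
  utils::write.csv(pc, path, row.names = FALSE)
  invisible(path)
}
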