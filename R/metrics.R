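#' Multi-class confusion matrix
#'
#' Cross-tabulates true against predicted grade labels. Rows are the actual
#' grades, columns the predicted grades.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors over the
#'   label set.
#' @param labels The admissible label values (default grades `0:4`).
#' @return A square integer matrix of class `confusion_matrix` with
#'   `dimnames` `(actual, predicted)`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, labels = 0:4) {
  if (length(true_labels) == 0L)
    stop("empty label sequences", call. = FALSE)
  if (length(true_labels) != length(predicted_labels))
    stop("label sequences have different lengths", call. = FALSE)
  if (!all(true_labels %in% labels) || !all(predicted_labels %in% labels))
    stop("labels outside the admissible set ",
         paste(range(labels), collapse = ".."), call. = FALSE)
  tab <- table(actual = factor(true_labels, levels = labels),
               predicted = factor(predicted_labels, levels = labels))
  structure(unclass(as.matrix(tab)), class = "confusion_matrix")
}

#' One-vs-rest decomposition of a confusion matrix
#'
#' For each class c: TP is the diagonal cell, FN the rest of row c, FP the
#' rest of column c, and TN the remainder; TP+TN+FP+FN equals the grand
#' total for every class.
#'
#' @param cm A square count matrix (class need not be `confusion_matrix`).
#' @return A `data.frame` with columns `class`, `TP`, `FN`, `FP`, `TN`.
#' @export
one_vs_rest <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  cls <- if (!is.null(rownames(cm))) rownames(cm) else as.character(seq_len(nrow(cm)) - 1L)
  data.frame(class = cls, TP = tp, FN = fn, FP = fp, TN = tn,
             row.names = NULL, stringsAsFactors = FALSE)
}

# a single one-vs-rest metric row; zero denominators yield 0
ovr_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- div(tp + tn, tp + tn + fp + fn)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  precision <- div(tp, tp + fp)
  f1 <- div(2 * precision * recall, precision + recall)
  fpr <- div(fp, fp + tn)
  fnr <- div(fn, fn + tp)
  fdr <- div(fp, fp + tp)
  npv <- div(tn, tn + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, 0)
  c(acc = acc, recall = recall, specificity = specificity,
    precision = precision, f1 = f1, fpr = fpr, fnr = fnr, fdr = fdr,
    npv = npv, mcc = mcc)
}

#' Ten-metric evaluation report from a confusion matrix
#'
#' Computes accuracy, recall (sensitivity), specificity, precision,
#' F1-score, false positive rate, false negative rate, false discovery
#' rate, negative predictive value and the Matthews correlation coefficient
#' from the one-vs-rest decomposition of each class, then averages across
#' classes. Macro averaging (the unweighted mean over classes) is the
#' default; micro averaging pools the per-class TP/TN/FP/FN first.
#' Metrics with a zero denominator are defined as 0 and the affected
#' classes are flagged in the `zero_denominator` attribute.
#'
#' @param cm A square count matrix with a positive total.
#' @param average `"macro"` (default) or `"micro"`.
#' @return A named numeric vector of the ten metrics, of class
#'   `metric_report`, with the per-class table in attribute `per_class`.
#' @export
metric_report <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- unclass(as.matrix(cm))
  if (sum(cm) == 0) stop("cannot evaluate an all-zero confusion matrix", call. = FALSE)
  d <- one_vs_rest(cm)
  per <- t(mapply(function(tp, tn, fp, fn) ovr_metrics(tp, tn, fp, fn),
                  d$TP, d$TN, d$FP, d$FN))
  rownames(per) <- d$class
  out <- if (average == "macro") colMeans(per) else
    ovr_metrics(sum(d$TP), sum(d$TN), sum(d$FP), sum(d$FN))
  zero <- d$class[(d$TP + d$FP == 0) | (d$TP + d$FN == 0) |
                  (d$TN + d$FP == 0) | (d$TN + d$FN == 0)]
  structure(out, class = "metric_report", per_class = per,
            average = average, zero_denominator = zero)
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("Evaluation metrics (", attr(x, "average"), "-averaged over ",
      nrow(attr(x, "per_class")), " classes)\n", sep = "")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, digits))
  if (length(attr(x, "zero_denominator")))
    cat("zero-denominator classes (metrics set to 0):",
        paste(attr(x, "zero_denominator"), collapse = ", "), "\n")
  invisible(x)
}
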