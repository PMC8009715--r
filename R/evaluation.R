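#' Multiclass confusion matrix
#'
#' Rows are actual classes, columns predicted classes:
#' `counts[i, j]` is the number of samples of true class `i` predicted
#' as class `j`.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param labels class labels fixing the matrix order; defaults to the
#'   sorted union of observed labels.  Labels outside this set are an
#'   error.
#' @return object of class `confusion_matrix` (an integer matrix with
#'   dimnames `actual` x `predicted`).
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' lengths differ")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% labels))
    stop("labels outside the declared label set")
  ft <- factor(y_true, levels = labels)
  fp <- factor(y_pred, levels = labels)
  counts <- unclass(table(actual = ft, predicted = fp))
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows actual, columns predicted):\n")
  print(unclass(x))
  cat(sprintf("correct: %d / %d\n", sum(diag(x)), sum(x)))
  invisible(x)
}

#' Per-class TP/TN/FP/FN counts
#'
#' One-vs-rest bookkeeping for a single class: TP is the diagonal cell,
#' FP the rest of its column, FN the rest of its row, and TN everything
#' else, so `TP + TN + FP + FN` equals the number of evaluated samples.
#'
#' @param cm a [confusion_matrix()].
#' @param class one of its class labels.
#' @return list with integer elements `TP`, `TN`, `FP`, `FN`.
#' @export
per_class_counts <- function(cm, class) {
  labs <- rownames(cm)
  i <- match(as.character(class), labs)
  if (is.na(i)) stop("unknown class: ", class)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(TP = as.integer(tp), TN = as.integer(tn),
       FP = as.integer(fp), FN = as.integer(fn))
}

ratio0 <- function(num, den, what) {
  if (den <= 0) {
    warning(what, ": zero denominator, returning 0")
    return(0)
  }
  num / den
}

#' Confusion-count metrics for one class
#'
#' The standard one-vs-rest ratios: sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive value
#' (precision) `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`,
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, and misclassification rate
#' `(FP+FN)/(TP+TN+FP+FN)`.  A zero denominator yields 0 with a warning.
#'
#' @param c list with `TP`, `TN`, `FP`, `FN` (see [per_class_counts()]).
#' @return the ratio as a plain number in `[0, 1]`.
#' @export
sensitivity <- function(c) ratio0(c$TP, c$TP + c$FN, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(c) ratio0(c$TN, c$TN + c$FP, "specificity")

#' @rdname sensitivity
#' @export
ppv <- function(c) ratio0(c$TP, c$TP + c$FP, "ppv")

#' @rdname sensitivity
#' @export
npv <- function(c) ratio0(c$TN, c$TN + c$FN, "npv")

#' @rdname sensitivity
#' @export
class_accuracy <- function(c)
  ratio0(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN, "accuracy")

#' @rdname sensitivity
#' @export
misclassification_rate <- function(c)
  ratio0(c$FP + c$FN, c$TP + c$TN + c$FP + c$FN, "misclassification")

#' F1 score from precision and recall
#'
#' `2 p r / (p + r)`, defined as 0 when `p + r = 0`.
#'
#' @param p precision, `r` recall.
#' @param r recall.
#' @return F1 in `[0, 1]`.
#' @export
f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Pooled F1 summaries of a multiclass confusion matrix
#'
#' `macro_f1` is the unweighted mean of the per-class F1 scores;
#' `micro_f1` pools TP/FP/FN over classes before forming F1 (for
#' single-label classification it equals overall accuracy);
#' `weighted_f1` weights per-class F1 by class support (row totals).
#'
#' @param cm a [confusion_matrix()].
#' @return the pooled score in `[0, 1]`.
#' @export
macro_f1 <- function(cm) mean(per_class_f1(cm))

#' @rdname macro_f1
#' @export
micro_f1 <- function(cm) {
  cs <- lapply(rownames(cm), function(l) per_class_counts(cm, l))
  tp <- sum(vapply(cs, `[[`, numeric(1L), "TP"))
  fp <- sum(vapply(cs, `[[`, numeric(1L), "FP"))
  fn <- sum(vapply(cs, `[[`, numeric(1L), "FN"))
  f1(ratio0(tp, tp + fp, "micro precision"),
     ratio0(tp, tp + fn, "micro recall"))
}

#' @rdname macro_f1
#' @export
weighted_f1 <- function(cm) {
  support <- rowSums(cm)
  sum(per_class_f1(cm) * support) / sum(support)
}

per_class_f1 <- function(cm) {
  vapply(rownames(cm), function(l) {
    c <- per_class_counts(cm, l)
    f1(ppv(c), sensitivity(c))
  }, numeric(1L))
}

#' Full per-class and pooled evaluation report
#'
#' @param cm a [confusion_matrix()].
#' @param percent report percentages rounded to 1 decimal instead of raw
#'   ratios (default `FALSE`).
#' @return list with `per_class` (data.frame: TP/TN/FP/FN, recall,
#'   specificity, precision, npv, f1, misclassification, accuracy per
#'   class) and `pooled` (micro/macro/weighted F1, misclassification,
#'   recall, specificity, precision, accuracy from pooled counts).
#' @export
classification_report <- function(cm, percent = FALSE) {
  labs <- rownames(cm)
  rows <- lapply(labs, function(l) {
    c <- per_class_counts(cm, l)
    data.frame(class = l, TP = c$TP, TN = c$TN, FP = c$FP, FN = c$FN,
               recall = sensitivity(c), specificity = specificity(c),
               precision = ppv(c), npv = npv(c),
               f1 = f1(ppv(c), sensitivity(c)),
               misclassification = misclassification_rate(c),
               accuracy = class_accuracy(c))
  })
  per_class <- do.call(rbind, rows)
  cs <- lapply(labs, function(l) per_class_counts(cm, l))
  pool <- list(TP = sum(vapply(cs, `[[`, numeric(1L), "TP")),
               TN = sum(vapply(cs, `[[`, numeric(1L), "TN")),
               FP = sum(vapply(cs, `[[`, numeric(1L), "FP")),
               FN = sum(vapply(cs, `[[`, numeric(1L), "FN")))
  pooled <- data.frame(
    micro_f1 = micro_f1(cm), macro_f1 = macro_f1(cm),
    weighted_f1 = weighted_f1(cm),
    misclassification = misclassification_rate(pool),
    recall = sensitivity(pool), specificity = specificity(pool),
    precision = ppv(pool), accuracy = class_accuracy(pool))
  if (percent) {
    num <- vapply(per_class, is.numeric, logical(1L)) &
      !names(per_class) %in% c("TP", "TN", "FP", "FN")
    per_class[num] <- round(per_class[num] * 100, 1)
    pooled[] <- round(pooled * 100, 1)
  }
  list(per_class = per_class, pooled = pooled)
}
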