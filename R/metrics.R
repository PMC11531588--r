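#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; defined as 0 (with a warning) when both
#' are zero.
#'
#' @param precision,recall values in `[0, 1]`
#' @return F1 in `[0, 1]`
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) {
    warning("precision and recall both zero; F1 defined as 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' ROC-AUC by midrank Mann-Whitney normalization
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted half (midranks) — the area under the ROC
#' curve traced as the decision threshold varies.
#'
#' @param scores numeric scores, larger = more positive
#' @param labels logical or 0/1 vector, TRUE/1 = positive
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC-AUC undefined: only one class present")
  }
  r <- rank(scores)                      # midranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged one-vs-rest ROC-AUC
#'
#' @param prob_matrix `n x K` class-probability matrix with class-named
#'   columns
#' @param labels character/factor true labels matching the column names
#' @return mean of the K one-vs-rest AUCs
#' @export
macro_roc_auc <- function(prob_matrix, labels) {
  classes <- colnames(prob_matrix)
  stopifnot(!is.null(classes), all(as.character(labels) %in% classes))
  mean(vapply(classes, function(cl) {
    roc_auc(prob_matrix[, cl], as.character(labels) == cl)
  }, numeric(1)))
}

#' Confusion matrix with fixed class order
#'
#' @param predicted,actual label vectors
#' @param classes class order for rows/columns
#' @return integer matrix, rows = actual, columns = predicted
#' @export
confusion_matrix <- function(predicted, actual, classes) {
  tab <- table(factor(actual, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

# per-class precision/recall/F1 from a confusion matrix (rows = actual)
per_class_f1 <- function(confusion) {
  classes <- rownames(confusion)
  vapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec == 0 && rec == 0) 0 else f1_score(prec, rec)
  }, numeric(1))
}

#' Classification report for a set of predictions
#'
#' Computes accuracy, F1 (binary: for the positive class; multiclass:
#' macro-averaged), ROC-AUC (binary or macro one-vs-rest), the confusion
#' matrix, and per-bucket accuracy.
#'
#' @param prob_matrix `n x K` probability matrix with class-named columns
#' @param labels true labels (characters matching column names)
#' @param buckets optional bucket id per sample for per-bucket accuracy
#' @param positive_class for the binary F1; defaults to the last column
#' @return object of class `metric_report`
#' @export
evaluate_predictions <- function(prob_matrix, labels, buckets = NULL,
                                 positive_class = NULL) {
  classes <- colnames(prob_matrix)
  labels <- as.character(labels)
  if (nrow(prob_matrix) == 0L) stop("empty test set")
  predicted <- classes[apply(prob_matrix, 1L, which.max)]
  acc <- mean(predicted == labels)
  conf <- confusion_matrix(predicted, labels, classes)
  binary <- length(classes) == 2L
  # per-fold test sets can lack a class; report NA rather than fail, the
  # pooled report over all folds always has every class
  auc_or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  if (binary) {
    pos <- positive_class %||% classes[2]
    f1v <- per_class_f1(conf)[[pos]]
    aucv <- auc_or_na(roc_auc(prob_matrix[, pos], labels == pos))
    rep <- list(accuracy = acc, f1 = f1v, roc_auc = aucv)
  } else {
    rep <- list(accuracy = acc, macro_f1 = mean(per_class_f1(conf)),
                macro_roc_auc = auc_or_na(macro_roc_auc(prob_matrix,
                                                        labels)))
  }
  rep$confusion <- conf
  rep$n <- length(labels)
  if (!is.null(buckets)) {
    rep$per_bucket_accuracy <- vapply(split(predicted == labels, buckets),
                                      mean, numeric(1))
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  keys <- intersect(c("accuracy", "f1", "roc_auc", "macro_f1",
                      "macro_roc_auc"), names(x))
  cat("<metric_report> n =", x$n, "\n")
  for (k in keys) cat(sprintf("  %-14s %.4f\n", k, x[[k]]))
  invisible(x)
}

#' Intensity-only baseline scores
#'
#' Reference classifier that scores each voxel by a summary intensity
#' statistic (mean or max) alone, with no learned spatial structure —
#' the floor against which the 3D network is compared.
#'
#' @param ds a [cnn_dataset()] or list of voxel arrays
#' @param stat `"mean"` or `"max"`
#' @return numeric score per voxel
#' @export
intensity_baseline_scores <- function(ds, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else max
  if (inherits(ds, "cnn_dataset")) {
    vapply(seq_len(ds$n), function(i) f(ds$get_x(i)), numeric(1))
  } else {
    vapply(ds, f, numeric(1))
  }
}
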