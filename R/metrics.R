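#' Per-class quality parameters for a classifier
#'
#' Evaluates a fitted PCA-LDA or SVM model on an external test set and
#' reports, per class, one-vs-rest accuracy, sensitivity and specificity
#' in percent, plus their unweighted macro averages -- the standard
#' "quality parameters" table for spectral classification. With
#' one-vs-rest counts TP/FN/TN/FP for class c over n test spectra:
#' sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' accuracy = 100 (TP+TN)/n.
#'
#' @param model a `pca_lda_model` or `rbf_svm_model` (anything with a
#'   `predict` method returning labels), or a character vector of
#'   predictions.
#' @param test a `spectrum_set` or matrix of test spectra (ignored when
#'   `model` is already a prediction vector).
#' @param labels true class labels (defaults to `plant_type` metadata).
#' @return a `class_metrics` object: data frame with columns `class`,
#'   `accuracy`, `sensitivity`, `specificity` and a final `Average` row;
#'   the full confusion matrix is attached as `attr(, "confusion")`.
#'   Classes absent from the test set have undefined sensitivity and are
#'   excluded from the macro averages with a warning.
#' @export
evaluate_classifier <- function(model, test = NULL, labels = NULL) {
  if (is.character(model)) {
    predicted <- model
  } else {
    if (is.null(test)) stop("test data required", call. = FALSE)
    predicted <- predict(model, test)
  }
  if (is.null(labels)) {
    if (!inherits(test, "spectrum_set")) {
      stop("labels are required when test is not a spectrum_set", call. = FALSE)
    }
    labels <- test$meta$plant_type
  }
  labels <- as.character(labels)
  if (length(predicted) != length(labels)) {
    stop("prediction/label length mismatch", call. = FALSE)
  }
  classes <- sort(unique(c(labels, predicted)))
  confusion <- table(factor(labels, classes), factor(predicted, classes),
                     dnn = c("true", "predicted"))
  metrics_from_confusion(confusion)
}

#' Quality parameters from a confusion matrix
#'
#' @param confusion square confusion matrix, rows = true classes,
#'   columns = predicted classes, identical dimnames.
#' @return a `class_metrics` object (see [evaluate_classifier()]).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(as.table(confusion))
  if (nrow(confusion) != ncol(confusion) ||
      !identical(rownames(confusion), colnames(confusion))) {
    stop("confusion matrix must be square with matching dimnames",
         call. = FALSE)
  }
  classes <- rownames(confusion)
  n <- sum(confusion)
  rows <- lapply(seq_along(classes), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = classes[k],
               accuracy = 100 * (tp + tn) / n,
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  absent <- is.na(df$sensitivity)
  if (any(absent)) {
    warning("class(es) with no test members excluded from macro averages: ",
            paste(df$class[absent], collapse = ", "))
  }
  avg <- data.frame(class = "Average",
                    accuracy = mean(df$accuracy[!absent]),
                    sensitivity = mean(df$sensitivity[!absent]),
                    specificity = mean(df$specificity[!absent]),
                    stringsAsFactors = FALSE)
  out <- rbind(df, avg)
  rownames(out) <- NULL
  structure(out, confusion = confusion, class = c("class_metrics",
                                                  "data.frame"))
}

#' @export
print.class_metrics <- function(x, ...) {
  df <- as.data.frame(x)
  df[, -1] <- lapply(df[, -1], function(v) sprintf("%.2f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Overall (micro) accuracy from a class_metrics object
#' @param metrics a `class_metrics` object.
#' @return overall percentage of correctly classified test spectra.
#' @export
overall_accuracy <- function(metrics) {
  cm <- attr(metrics, "confusion")
  100 * sum(diag(cm)) / sum(cm)
}
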