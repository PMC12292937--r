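# Classification metrics --------------------------------------------------

#' Confusion matrix of predictions
#'
#' @param truth,pred integer class labels of equal length.
#' @param classes class levels (default: sorted union).
#' @return A `length(classes)` square count matrix; rows are true
#'   classes, columns predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = as.character(classes),
                              predicted = as.character(classes)))
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the marginal products. The degenerate case `p_e = 1`
#' (all mass in one row/column pair) is defined as 0 with a warning.
#'
#' @param confusion non-negative count matrix with positive total.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) <= 0)
    stop("confusion matrix must be non-negative with positive total")
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate confusion matrix (expected agreement 1): kappa = 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Accuracy, kappa and confusion counts of predictions
#'
#' @inheritParams confusion_matrix
#' @return A list of class `mi_metrics` with `accuracy`, `kappa` and
#'   `confusion`.
#' @export
classification_metrics <- function(truth, pred, classes = NULL) {
  if (!length(truth)) stop("empty test set")
  cm <- confusion_matrix(truth, pred, classes)
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 kappa = cohen_kappa(cm), confusion = cm),
            class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f, kappa %.3f\n", x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}
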