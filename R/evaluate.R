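# Classification evaluation: confusion matrices, accuracy, the Matthews
# correlation coefficient, and the leave-one-out cross-validation harness.

#' Build a confusion matrix
#'
#' @param truth true class labels.
#' @param predicted predicted labels, same length.
#' @param positive for binary problems, the class counted as positive
#'   (defaults to the first sorted label).
#' @param classes optional full label set (so absent classes keep a row).
#' @return An object of class `confusion_matrix`: a k x k contingency
#'   table (rows = truth, columns = predicted) with attribute `positive`.
#' @export
confusion_matrix <- function(truth, predicted, positive = NULL,
                             classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  tab <- table(truth = factor(truth, levels = classes),
               predicted = factor(predicted, levels = classes))
  if (is.null(positive)) positive <- classes[1]
  structure(tab, positive = positive, class = c("confusion_matrix", "table"))
}

# TP/TN/FP/FN counts of a binary confusion matrix.
.binary_counts <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (nrow(cm) != 2) stop("binary confusion matrix required")
  pos <- attr(cm, "positive")
  neg <- setdiff(rownames(cm), pos)
  list(TP = cm[pos, pos], TN = cm[neg, neg],
       FP = cm[neg, pos], FN = cm[pos, neg])
}

#' Classification accuracy
#'
#' Fraction of correctly classified samples: the trace of the confusion
#' matrix over its total.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(unclass(cm))) / total
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` for a
#' binary confusion matrix. Values near +1 indicate perfect prediction,
#' near 0 random prediction, near -1 complete disagreement. When any
#' factor of the denominator is zero the classifier is uninformative and
#' 0 is returned (the "random prediction" value).
#'
#' @param cm a binary [confusion_matrix()] (or TP/TN/FP/FN via `counts`).
#' @param counts optional named list/vector with elements TP, TN, FP, FN,
#'   used instead of `cm`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm = NULL, counts = NULL) {
  b <- if (!is.null(counts)) as.list(counts) else .binary_counts(cm)
  TP <- as.numeric(b$TP); TN <- as.numeric(b$TN)
  FP <- as.numeric(b$FP); FN <- as.numeric(b$FN)
  den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den2 == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den2)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted)\n")
  m <- unclass(x)
  attr(m, "positive") <- NULL
  print(m)
  cat(sprintf("Accuracy: %.3f", accuracy(x)))
  if (nrow(x) == 2) cat(sprintf("   MCC: %.3f (positive class '%s')",
                                mcc(x), attr(x, "positive")))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validation of a disease-signature predictor
#'
#' For each sample s, a model is trained on all remaining samples and used
#' to predict s, so no predictor ever sees its own test sample. All
#' data-dependent preprocessing (feature imputation means,
#' standardization) is recomputed inside each fold from the training
#' samples only. The feature index (which cells are measured) is built
#' once on the full panel; it depends on the measurement mask, not on the
#' labels.
#'
#' A fold whose training set loses a class entirely (class of size 1) is
#' skipped with a warning and recorded.
#'
#' @param panel a [sample_panel()].
#' @param label_field metadata column holding the class label.
#' @param classifier `"svm"` or `"tree"`.
#' @param config an [svm_config()].
#' @param missing_policy passed to [build_feature_index()].
#' @param ... further arguments passed to [dsp()] (e.g. `standardize`,
#'   `min_leaf`).
#' @return An object of class `dsp_cv`: per-sample predictions (with
#'   decision values for the binary SVM), the confusion matrix, accuracy,
#'   and MCC (binary problems).
#' @export
loocv <- function(panel, label_field = "mll_status",
                  classifier = c("svm", "tree"), config = svm_config(),
                  missing_policy = "intersect", ...) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(panel, "sample_panel"))
  y <- panel_labels(panel, label_field)
  classes <- sort(unique(y))
  if (any(table(y) < 2)) {
    warning("classes of size 1 present: their folds will be skipped")
  }
  n <- length(panel)
  index <- build_feature_index(panel, missing_policy)
  pred <- rep(NA_character_, n)
  decision <- rep(NA_real_, n)
  skipped <- logical(n)
  for (s in seq_len(n)) {
    train <- panel[-s]
    if (length(unique(panel_labels(train, label_field))) < 2) {
      skipped[s] <- TRUE
      next
    }
    fit <- dsp(train, label_field, classifier, config, index = index, ...)
    pred[s] <- predict(fit, panel$matrices[[s]])
    if (classifier == "svm" && length(classes) == 2) {
      decision[s] <- predict(fit, panel$matrices[[s]], type = "decision")
    }
  }
  ok <- !skipped
  cm <- confusion_matrix(y[ok], pred[ok], classes = classes)
  res <- data.frame(sample_id = panel$meta$sample_id, truth = y,
                    predicted = pred, decision = decision,
                    skipped = skipped, stringsAsFactors = FALSE)
  structure(list(samples = res, confusion = cm, accuracy = accuracy(cm),
                 mcc = if (length(classes) == 2) mcc(cm) else NA_real_,
                 label_field = label_field, classifier = classifier,
                 n_skipped = sum(skipped)),
            class = "dsp_cv")
}

#' @export
print.dsp_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%s on '%s'): %d samples%s\n",
              x$classifier, x$label_field, nrow(x$samples),
              if (x$n_skipped) sprintf(" (%d folds skipped)", x$n_skipped)
              else ""))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.dsp_cv <- function(object, ...) {
  print(object)
  s <- object$samples
  wrong <- s[!s$skipped & s$truth != s$predicted, , drop = FALSE]
  if (nrow(wrong)) {
    cat("Misclassified samples:\n")
    print(wrong[, c("sample_id", "truth", "predicted")], row.names = FALSE)
  }
  invisible(object)
}
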