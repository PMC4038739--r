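# End-to-end experiment orchestration: the two cross-validated
# classification experiments (MLL status; fusion subtype) and the
# train-then-classify-de-novo workflow, each from raw matrices through
# normalization to a JSON-able report.

.report_cv <- function(cv) {
  list(confusion = as.list(as.data.frame(unclass(cv$confusion))),
       accuracy = cv$accuracy, mcc = cv$mcc,
       samples = cv$samples)
}

#' Run the leukemia-type classification experiment
#'
#' Normalizes every sample of a raw panel, then runs leave-one-out
#' cross-validation of the binary SVM on the MLL status label
#' (fusion vs wild-type).
#'
#' @param panel a raw [sample_panel()] (or the output of
#'   [simulate_panel()]`$panel`).
#' @param config an [svm_config()].
#' @param norm a [norm_config()]; `NULL` skips normalization (input
#'   already normalized).
#' @param classifier `"svm"` or `"tree"`.
#' @return list with the fitted cross-validation (`cv`), the normalized
#'   panel, and a plain-list `report`.
#' @export
run_type_experiment <- function(panel, config = svm_config(),
                                norm = norm_config(),
                                classifier = "svm") {
  if (!is.null(norm)) panel <- normalize_panel(panel, norm)
  cv <- loocv(panel, "mll_status", classifier = classifier, config = config)
  list(cv = cv, panel = panel, report = .report_cv(cv))
}

#' Run the fusion-subtype classification experiment
#'
#' Restricts the panel to fusion samples and cross-validates the
#' classifier on the subtype label (MLL-AF9 vs MLL-ENL in the two-subtype
#' design; one-vs-one voting when more subtypes are present).
#'
#' @inheritParams run_type_experiment
#' @return as [run_type_experiment()].
#' @export
run_subtype_experiment <- function(panel, config = svm_config(),
                                   norm = norm_config(),
                                   classifier = "svm") {
  keep <- panel$meta$mll_status == "fusion" & panel$meta$subtype != "none"
  sub <- panel[which(keep)]
  if (length(unique(sub$meta$subtype)) < 2) {
    stop("need at least two fusion subtypes")
  }
  if (!is.null(norm)) sub <- normalize_panel(sub, norm)
  cv <- loocv(sub, "subtype", classifier = classifier, config = config)
  list(cv = cv, panel = sub, report = .report_cv(cv))
}

#' Train on one panel and classify a second panel de novo
#'
#' Fits a single model on the full training panel and predicts every
#' sample of an independent test panel (projected onto the training
#' feature index; sample ids must be disjoint).
#'
#' @param train_panel,test_panel raw [sample_panel()] objects sharing a
#'   fragment map.
#' @param label_field class label column.
#' @param config an [svm_config()].
#' @param norm a [norm_config()]; `NULL` skips normalization.
#' @return list with the fitted model (`fit`), per-sample predictions,
#'   confusion matrix, accuracy and MCC (binary labels).
#' @export
run_denovo <- function(train_panel, test_panel,
                       label_field = "mll_status",
                       config = svm_config(), norm = norm_config()) {
  if (length(intersect(train_panel$meta$sample_id,
                       test_panel$meta$sample_id))) {
    stop("training and test sample ids must be disjoint")
  }
  if (!is.null(norm)) {
    train_panel <- normalize_panel(train_panel, norm)
    if (length(test_panel)) test_panel <- normalize_panel(test_panel, norm)
  }
  fit <- dsp(train_panel, label_field, config = config)
  if (!length(test_panel)) {
    warning("empty test panel: nothing to classify")
    return(list(fit = fit, samples = data.frame(), confusion = NULL,
                accuracy = NA_real_, mcc = NA_real_))
  }
  truth <- panel_labels(test_panel, label_field)
  pred <- predict(fit, test_panel)
  cm <- confusion_matrix(truth, pred, classes = fit$classes)
  list(fit = fit,
       samples = data.frame(sample_id = test_panel$meta$sample_id,
                            truth = truth, predicted = pred,
                            stringsAsFactors = FALSE),
       confusion = cm, accuracy = accuracy(cm),
       mcc = if (nrow(cm) == 2) mcc(cm) else NA_real_)
}

#' Write an experiment report as JSON
#'
#' @param report a report list from one of the `run_*` functions (the
#'   `report` element) or any JSON-able list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
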