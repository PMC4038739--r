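# The disease-signature predictor: the user-facing fitted model. Wraps
# feature vectorization, optional per-feature standardization, and the
# SMO-trained polynomial-kernel SVM (or the information-gain tree) into a
# single classed object with the usual fit/predict/print/summary surface.

#' Fit a chromatin conformation disease-signature predictor
#'
#' Trains a classifier on the vectorized interaction frequencies of a
#' labeled 5C panel. Features (fragment-pair IFs) are standardized to zero
#' mean and unit variance by default, with the statistics learned on the
#' training samples only; a polynomial-kernel SVM (binary, or one-vs-one
#' for more than two classes) or an information-gain decision tree does the
#' classification.
#'
#' @param panel a [sample_panel()] of (normalized) contact matrices.
#' @param label_field metadata column used as the class label
#'   (`"mll_status"` or `"subtype"`).
#' @param classifier `"svm"` or `"tree"`.
#' @param config an [svm_config()] (ignored for the tree).
#' @param min_leaf tree minimum leaf size (ignored for the SVM).
#' @param missing_policy passed to [build_feature_index()].
#' @param standardize standardize features before the SVM.
#' @param index optional precomputed [build_feature_index()] (e.g. from a
#'   training panel when refitting).
#' @return An object of class `dsp`: the fitted model plus the feature
#'   index, imputation means and standardization statistics needed to
#'   project new samples into the training feature space.
#' @examples
#' sim <- simulate_panel(hoxa_design(seed = 42))
#' norm <- normalize_panel(sim$panel)
#' fit <- dsp(norm, "mll_status")
#' fit
#' @export
dsp <- function(panel, label_field = "mll_status",
                classifier = c("svm", "tree"), config = svm_config(),
                min_leaf = 1, missing_policy = "intersect",
                standardize = TRUE, index = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(panel, "sample_panel"))
  y <- panel_labels(panel, label_field)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes to train")
  if (is.null(index)) index <- build_feature_index(panel, missing_policy)
  X <- feature_matrix(panel, index)
  feature_means <- attr(X, "feature_means")
  center <- scale_sd <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, stats::sd)
    scale_sd[scale_sd == 0 | is.na(scale_sd)] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_sd, `/`)
  }
  model <- if (classifier == "svm") {
    if (length(classes) == 2) svm_train(X, y, config, class_labels = classes)
    else svm_train_multiclass(X, y, config)
  } else {
    tree_train(X, y, min_leaf)
  }
  structure(list(model = model, classifier = classifier,
                 label_field = label_field, classes = classes,
                 index = index, feature_means = feature_means,
                 center = center, scale_sd = scale_sd,
                 config = config, n_train = length(panel),
                 sample_ids = panel$meta$sample_id),
            class = "dsp")
}

# Project a panel (or single contact matrix) onto a fitted model's feature
# space, applying the training imputation means and standardization.
.dsp_features <- function(object, newdata) {
  if (inherits(newdata, "contact_matrix")) {
    X <- rbind(vectorize(newdata, object$index,
                         feature_means = object$feature_means))
  } else if (inherits(newdata, "sample_panel")) {
    raw <- do.call(rbind, lapply(newdata$matrices,
                                 function(m) m$values[cbind(object$index$i,
                                                            object$index$j)]))
    if (anyNA(raw)) {
      if (attr(object$index, "missing_policy") == "intersect") {
        stop("unmeasured cell in new data under the 'intersect' policy")
      }
      na <- which(is.na(raw), arr.ind = TRUE)
      raw[na] <- object$feature_means[na[, 2]]
    }
    X <- raw
  } else {
    X <- rbind(newdata)
    if (ncol(X) != nrow(object$index)) {
      stop("newdata does not match the model's feature index")
    }
  }
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale_sd, `/`)
  }
  X
}

#' Predict classes for new 5C samples
#'
#' @param object a fitted [dsp()] model.
#' @param newdata a [sample_panel()], a single [contact_matrix()], or a
#'   numeric feature matrix already aligned to the model's feature index.
#' @param type `"class"` for labels, `"decision"` for decision values
#'   (binary SVM only).
#' @param ... ignored.
#' @return character labels (or decision values).
#' @export
predict.dsp <- function(object, newdata, type = c("class", "decision"),
                        ...) {
  type <- match.arg(type)
  X <- .dsp_features(object, newdata)
  if (type == "decision") {
    if (!inherits(object$model, "smo_svm")) {
      stop("decision values are available for the binary SVM only")
    }
    return(predict(object$model, X, type = "decision"))
  }
  predict(object$model, X)
}

#' @export
print.dsp <- function(x, ...) {
  cat(sprintf(
    "Disease-signature predictor (%s) on '%s': %d classes, %d features, %d training samples\n",
    if (x$classifier == "svm") "polynomial-kernel SVM" else "decision tree",
    x$label_field, length(x$classes), nrow(x$index), x$n_train))
  print(x$model)
  invisible(x)
}

#' @export
summary.dsp <- function(object, ...) {
  print(object)
  if (inherits(object$model, "smo_svm")) {
    a <- object$model$alpha
    cat(sprintf("Dual: %d/%d alphas > 0, %d at bound C = %g, sum(alpha*y) = %.2e\n",
                sum(a > 1e-8), length(a),
                sum(a > object$config$cost - 1e-8), object$config$cost,
                sum(a * object$model$y)))
  }
  invisible(object)
}

#' Per-contact weights of a linear disease-signature predictor
#'
#' For a binary SVM with a degree-1 homogeneous kernel the decision
#' function is linear; the weight vector (in standardized feature units)
#' is returned aligned to the feature index.
#'
#' @param object a fitted [dsp()] model.
#' @param ... ignored.
#' @return named numeric vector of per-pair weights.
#' @export
coef.dsp <- function(object, ...) {
  m <- object$model
  if (!inherits(m, "smo_svm") || m$config$degree != 1 ||
      m$config$offset != 0) {
    stop("coefficients are defined for the degree-1 homogeneous SVM only")
  }
  w <- drop(crossprod(m$support_vectors, m$dual_coefs))
  names(w) <- sprintf("%d-%d", object$index$i, object$index$j)
  w
}

#' Serialize a fitted predictor to JSON
#'
#' Writes a versioned JSON document holding the support vectors, dual
#' coefficients, bias, configuration, feature index and preprocessing
#' statistics; [read_dsp()] restores a working model.
#'
#' @param object a fitted [dsp()] model (SVM classifier only).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_dsp <- function(object, path) {
  stopifnot(inherits(object, "dsp"))
  if (object$classifier != "svm") stop("only SVM models are serialized")
  ser_svm <- function(m) list(
    # flattened row-major with explicit dims: avoids JSON shape ambiguity
    support_vectors = as.vector(t(m$support_vectors)),
    sv_dim = dim(m$support_vectors),
    dual_coefs = m$dual_coefs, bias = m$bias,
    class_labels = m$class_labels,
    degree = m$config$degree, cost = m$config$cost,
    offset = m$config$offset)
  models <- if (inherits(object$model, "smo_svm")) list(ser_svm(object$model))
  else lapply(object$model$models, ser_svm)
  names(models) <- sprintf("m%d", seq_along(models))  # keep a JSON object
  doc <- list(format = "chromsig-dsp", version = 1L,
              label_field = object$label_field, classes = object$classes,
              index = list(i = object$index$i, j = object$index$j,
                           n_frag = attr(object$index, "n_frag"),
                           missing_policy = attr(object$index,
                                                 "missing_policy")),
              feature_means = object$feature_means,
              center = object$center, scale_sd = object$scale_sd,
              models = models)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a serialized predictor
#'
#' @param path JSON path written by [write_dsp()].
#' @return a [dsp()] model.
#' @export
read_dsp <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "chromsig-dsp")) {
    stop("not a serialized disease-signature predictor")
  }
  idx <- data.frame(i = doc$index$i, j = doc$index$j)
  attr(idx, "n_frag") <- doc$index$n_frag
  attr(idx, "missing_policy") <- doc$index$missing_policy
  class(idx) <- c("feature_index", "data.frame")
  de_svm <- function(m) {
    cfg <- svm_config(degree = m$degree, cost = m$cost, offset = m$offset)
    sv <- matrix(m$support_vectors, nrow = m$sv_dim[1],
                 ncol = m$sv_dim[2], byrow = TRUE)
    structure(list(support_vectors = sv,
                   dual_coefs = m$dual_coefs, bias = m$bias,
                   config = cfg, class_labels = m$class_labels,
                   alpha = abs(m$dual_coefs),
                   y = sign(m$dual_coefs),
                   n_train = length(m$dual_coefs)),
              class = "smo_svm")
  }
  models <- unname(lapply(doc$models, de_svm))
  model <- if (length(models) == 1) models[[1]]
  else structure(list(models = models, classes = doc$classes),
                 class = "ovo_svm")
  structure(list(model = model, classifier = "svm",
                 label_field = doc$label_field, classes = doc$classes,
                 index = idx, feature_means = doc$feature_means,
                 center = doc$center, scale_sd = doc$scale_sd,
                 config = if (inherits(model, "smo_svm")) model$config
                 else models[[1]]$config,
                 n_train = NA_integer_, sample_ids = NULL),
            class = "dsp")
}
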