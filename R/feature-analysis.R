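# Discriminatory-contact identification: class-averaged and difference IF
# maps, per-contact information gain, and two-sample t-test filtering.
# "Informative contacts" are the pairs whose IFs differ significantly
# between classes (two-sided t-test, P < alpha, no multiple-testing
# correction) and carry positive information gain.

#' Class-averaged and difference IF maps
#'
#' Cell-wise arithmetic means per class over measured values, their
#' standard errors, and the difference map (first class minus second, in
#' sorted label order). A cell unmeasured in an entire class is unmeasured
#' in that class's output.
#'
#' @param panel a [sample_panel()].
#' @param label_field binary label column.
#' @return list with `means` (named list of matrices), `sems` (standard
#'   errors of the mean), `difference` (matrix), `classes`.
#' @export
class_mean_maps <- function(panel, label_field = "mll_status") {
  y <- panel_labels(panel, label_field)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("binary label required")
  per_class <- lapply(classes, function(cl) {
    mats <- lapply(panel$matrices[y == cl], `[[`, "values")
    arr <- simplify2array(mats)
    k <- rowSums(!is.na(arr), dims = 2)
    mu <- rowMeans(arr, na.rm = TRUE, dims = 2)
    mu[k == 0] <- NA
    sdv <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
    sem <- sdv / sqrt(pmax(k, 1))
    sem[k == 0] <- NA
    dimnames(mu) <- dimnames(sem) <- NULL
    list(mean = mu, sem = sem)
  })
  names(per_class) <- classes
  list(means = lapply(per_class, `[[`, "mean"),
       sems = lapply(per_class, `[[`, "sem"),
       difference = per_class[[1]]$mean - per_class[[2]]$mean,
       classes = classes)
}

# Vectorized two-sample t-tests over feature-matrix columns. Welch by
# default; var_equal = TRUE gives the pooled-variance Student variant.
# Degenerate columns (zero variance in both groups): equal means -> t = 0,
# p = 1; unequal means -> p = 0 with a warning.
.ttest_columns <- function(X, grp, var_equal = FALSE) {
  g1 <- X[grp, , drop = FALSE]
  g2 <- X[!grp, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var)
  v2 <- apply(g2, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0 | !is.finite(se)
  if (any(degen)) {
    eq <- degen & abs(m1 - m2) < .Machine$double.eps^0.5
    t[eq] <- 0; p[eq] <- 1
    ne <- degen & !eq
    if (any(ne)) {
      warning(sprintf(
        "%d feature(s) with zero within-group variance but unequal means (p set to 0)",
        sum(ne)), call. = FALSE)
      t[ne] <- sign(m1[ne] - m2[ne]) * Inf
      p[ne] <- 0
    }
  }
  list(t = t, p = p, mean1 = m1, mean2 = m2,
       sem1 = sqrt(v1 / n1), sem2 = sqrt(v2 / n2))
}

#' Per-contact two-sample t-tests
#'
#' Tests every fragment-pair feature for a class difference in mean IF
#' with a two-sided two-sample t-test. No multiple-testing correction is
#' applied by default (each feature is tested independently); an optional
#' Benjamini-Hochberg adjustment is available and clearly changes the
#' `passes` flag semantics to an FDR criterion.
#'
#' @param panel a [sample_panel()].
#' @param label_field binary label column.
#' @param alpha significance threshold (default 0.01).
#' @param var_equal `FALSE` (default) for the Welch test, `TRUE` for the
#'   pooled-variance Student variant.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param index optional precomputed [build_feature_index()].
#' @return An object of class `feature_scores`: a data frame with one row
#'   per feature-index pair — `i`, `j`, class means and standard errors,
#'   `diff`, `t_stat`, `p_value`, `passes`.
#' @export
ttest_contacts <- function(panel, label_field = "mll_status", alpha = 0.01,
                           var_equal = FALSE, adjust = c("none", "BH"),
                           index = NULL) {
  adjust <- match.arg(adjust)
  y <- panel_labels(panel, label_field)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("binary label required")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  if (is.null(index)) index <- build_feature_index(panel)
  X <- feature_matrix(panel, index)
  tt <- .ttest_columns(X, y == classes[1], var_equal = var_equal)
  p <- if (adjust == "BH") stats::p.adjust(tt$p, "BH") else tt$p
  out <- data.frame(i = index$i, j = index$j,
                    mean_class1 = tt$mean1, mean_class2 = tt$mean2,
                    sem_class1 = tt$sem1, sem_class2 = tt$sem2,
                    diff = tt$mean1 - tt$mean2,
                    t_stat = tt$t, p_value = p,
                    passes = p < alpha)
  attr(out, "classes") <- classes
  attr(out, "alpha") <- alpha
  attr(out, "n_frag") <- attr(index, "n_frag")
  class(out) <- c("feature_scores", "data.frame")
  out
}

#' Rank discriminatory contacts by information gain
#'
#' Joins the per-contact information gain (over the MDL supervised
#' discretization) with the two-sided t-test: informative contacts are the
#' pairs that pass the t-test filter (P < alpha) and carry positive
#' information gain. Rows are sorted by decreasing information gain, ties
#' by (i, j) order.
#'
#' @inheritParams ttest_contacts
#' @return a `feature_scores` data frame with additional columns
#'   `info_gain_bits` and `informative`, sorted by decreasing gain.
#' @export
rank_informative_contacts <- function(panel, label_field = "mll_status",
                                      alpha = 0.01, var_equal = FALSE,
                                      index = NULL) {
  if (is.null(index)) index <- build_feature_index(panel)
  scores <- ttest_contacts(panel, label_field, alpha,
                           var_equal = var_equal, index = index)
  y <- panel_labels(panel, label_field)
  X <- feature_matrix(panel, index)
  ig <- apply(X, 2, information_gain, labels = y)
  scores$info_gain_bits <- ig
  scores$informative <- scores$passes & ig > 0
  o <- order(-scores$info_gain_bits, scores$i, scores$j)
  out <- scores[o, ]
  rownames(out) <- NULL
  class(out) <- c("feature_scores", "data.frame")
  attr(out, "classes") <- attr(scores, "classes")
  attr(out, "alpha") <- attr(scores, "alpha")
  attr(out, "n_frag") <- attr(scores, "n_frag")
  out
}

#' @export
print.feature_scores <- function(x, ...) {
  cat(sprintf("Per-contact scores: %d fragment pairs (classes %s, alpha = %g)\n",
              nrow(x), paste(attr(x, "classes"), collapse = " vs "),
              attr(x, "alpha")))
  if (!is.null(x$informative)) {
    cat(sprintf("%d informative contact(s): t-test P < %g and info gain > 0\n",
                sum(x$informative), attr(x, "alpha")))
  }
  print(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Heatmap of per-contact scores
#'
#' Renders a score column (information gain by default) of a
#' `feature_scores` table as a fragment x fragment heatmap.
#'
#' @param x a `feature_scores` table.
#' @param column score column to map.
#' @param ... passed to [plot_if_map()].
#' @return invisibly, the plotted matrix.
#' @export
plot.feature_scores <- function(x, column = "info_gain_bits", ...) {
  stopifnot(column %in% names(x))
  n <- attr(x, "n_frag")
  v <- matrix(NA_real_, n, n)
  v[cbind(x$i, x$j)] <- x[[column]]
  v[cbind(x$j, x$i)] <- x[[column]]
  plot_if_map(v, main = column, ...)
  invisible(v)
}
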