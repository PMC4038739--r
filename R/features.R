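# Contact-to-feature vectorization: each 5C dataset becomes one vector of
# normalized IF values, indexed by a deterministic ordering of fragment
# pairs (row-major over the upper triangle). The classifier and the
# feature-ranking statistics all operate on this representation.

#' Build a feature index over a panel
#'
#' Enumerates the fragment pairs (i, j), i <= j, that form the classifier's
#' feature space, in row-major upper-triangle order. Diagonal cells
#' (self-ligation, i = j) are excluded by default: 5C measures junctions
#' between distinct fragments.
#'
#' @param panel a [sample_panel()].
#' @param missing_policy `"intersect"` keeps only pairs measured in every
#'   sample; `"impute_row_mean"` keeps pairs measured in at least 50% of
#'   samples (missing entries later imputed with the per-feature mean over
#'   samples where measured).
#' @param include_diagonal include i = j cells.
#' @return An object of class `feature_index`: a data frame with columns
#'   `i`, `j` and attributes `n_frag` and `missing_policy`.
#' @export
build_feature_index <- function(panel,
                                missing_policy = c("intersect",
                                                   "impute_row_mean"),
                                include_diagonal = FALSE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "sample_panel"), length(panel) > 0)
  n <- n_frag(panel$matrices[[1]])
  cnt <- Reduce(`+`, lapply(panel$matrices, function(m) measured(m) * 1L))
  keep <- if (missing_policy == "intersect") cnt == length(panel) else
    cnt >= length(panel) / 2
  ii <- row(keep); jj <- col(keep)
  upper <- ii < jj | (include_diagonal & ii == jj)
  sel <- which(upper & keep)
  # row-major upper triangle: order by i then j
  o <- order(ii[sel], jj[sel])
  sel <- sel[o]
  if (!length(sel)) {
    stop("degenerate feature space: no pair satisfies the missing policy")
  }
  idx <- data.frame(i = ii[sel], j = jj[sel])
  attr(idx, "n_frag") <- n
  attr(idx, "missing_policy") <- missing_policy
  class(idx) <- c("feature_index", "data.frame")
  idx
}

#' Vectorize a contact matrix along a feature index
#'
#' @param m a [contact_matrix()].
#' @param idx a [build_feature_index()] result.
#' @param feature_means per-feature means used to fill unmeasured cells
#'   under the `impute_row_mean` policy (from [feature_matrix()] training
#'   data); ignored under `intersect`.
#' @return numeric feature vector aligned to `idx`.
#' @export
vectorize <- function(m, idx, feature_means = NULL) {
  stopifnot(inherits(m, "contact_matrix"), inherits(idx, "feature_index"))
  if (n_frag(m) != attr(idx, "n_frag")) {
    stop("matrix dimension does not match feature index")
  }
  v <- m$values[cbind(idx$i, idx$j)]
  if (anyNA(v)) {
    if (attr(idx, "missing_policy") == "intersect") {
      stop("unmeasured cell encountered under the 'intersect' policy")
    }
    if (is.null(feature_means)) {
      stop("feature_means required to impute unmeasured cells")
    }
    v[is.na(v)] <- feature_means[is.na(v)]
  }
  v
}

#' Write a feature vector back into matrix form
#'
#' Inverse of [vectorize()] on measured cells: returns an n x n symmetric
#' matrix with the vector's values at the indexed pairs and `NA` elsewhere.
#'
#' @param v numeric vector aligned to `idx`.
#' @param idx a [build_feature_index()] result.
#' @return numeric matrix.
#' @export
devectorize <- function(v, idx) {
  n <- attr(idx, "n_frag")
  out <- matrix(NA_real_, n, n)
  out[cbind(idx$i, idx$j)] <- v
  out[cbind(idx$j, idx$i)] <- v
  out
}

#' Feature matrix of a panel
#'
#' Stacks the per-sample feature vectors into a samples x features matrix.
#' Under the `impute_row_mean` policy, unmeasured entries are filled with
#' the per-feature mean over the samples where the cell was measured (the
#' imputation statistics are returned so they can be reused on held-out
#' data).
#'
#' @param panel a [sample_panel()].
#' @param idx a [build_feature_index()] result (built on `panel` or a
#'   compatible training panel).
#' @return numeric matrix with rownames = sample ids; attribute
#'   `feature_means` carries the imputation means.
#' @export
feature_matrix <- function(panel, idx) {
  raw <- do.call(rbind, lapply(panel$matrices,
                               function(m) m$values[cbind(idx$i, idx$j)]))
  rownames(raw) <- panel$meta$sample_id
  fmeans <- colMeans(raw, na.rm = TRUE)
  if (anyNA(raw)) {
    if (attr(idx, "missing_policy") == "intersect") {
      stop("unmeasured cell encountered under the 'intersect' policy")
    }
    na <- which(is.na(raw), arr.ind = TRUE)
    raw[na] <- fmeans[na[, 2]]
  }
  attr(raw, "feature_means") <- fmeans
  raw
}
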