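# Information-gain decision tree: the simple alternative classifier used
# for comparisons against the SVM. Recursive binary splits on the
# (feature, threshold) pair maximizing plain information gain, thresholds
# at midpoints between sorted distinct values.

# All candidate (feature, threshold, gain) splits of X, by immediate
# information gain; NULL if no admissible threshold exists.
.tree_splits <- function(X, y) {
  n <- length(y)
  H <- .entropy(y)
  out <- list()
  for (f in seq_len(ncol(X))) {
    v <- X[, f]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    distinct <- which(diff(vs) > 0)
    for (b in distinct) {
      thr <- (vs[b] + vs[b + 1]) / 2
      gain <- H - (b / n) * .entropy(ys[seq_len(b)]) -
        ((n - b) / n) * .entropy(ys[-seq_len(b)])
      out[[length(out) + 1]] <- list(feature = f, threshold = thr,
                                     gain = gain)
    }
  }
  if (length(out)) out else NULL
}

# Best split: maximize immediate gain; if every candidate has zero gain
# (XOR-type parity structure), fall back to a one-step lookahead — pick the
# zero-gain split whose children's best splits recover the most gain.
# Returns NULL when neither criterion finds anything to gain.
.tree_best_split <- function(X, y) {
  cand <- .tree_splits(X, y)
  if (is.null(cand)) return(NULL)
  gains <- vapply(cand, `[[`, 0, "gain")
  if (max(gains) > 1e-12) return(cand[[which.max(gains)]])
  n <- length(y)
  look <- vapply(cand, function(sp) {
    left <- X[, sp$feature] <= sp$threshold
    child_gain <- function(sel) {
      if (length(unique(y[sel])) < 2) return(0)
      cs <- .tree_splits(X[sel, , drop = FALSE], y[sel])
      if (is.null(cs)) 0 else max(vapply(cs, `[[`, 0, "gain"))
    }
    (sum(left) / n) * child_gain(left) +
      (sum(!left) / n) * child_gain(!left)
  }, 0)
  if (max(look) <= 1e-12) return(NULL)
  sp <- cand[[which.max(look)]]
  sp$gain <- 0
  sp$lookahead <- max(look)
  sp
}

.majority <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # tie: first label in sort order
}

#' Train an information-gain decision tree
#'
#' Recursive binary splits on the (feature, threshold) maximizing the
#' information gain of the class labels, thresholds at midpoints between
#' sorted distinct values. When every immediate split has zero gain on an
#' impure node (parity structure such as XOR), a one-step lookahead picks
#' the split whose children recover the most gain. A node becomes a leaf
#' (majority label, ties to the first label) when it is pure, no split —
#' immediate or lookahead — gains information, or it has fewer than
#' `2 * min_leaf` samples. No pruning.
#'
#' @param X numeric matrix, samples in rows.
#' @param y class labels.
#' @param min_leaf minimum samples per leaf.
#' @return An object of class `ig_tree`.
#' @export
tree_train <- function(X, y, min_leaf = 1) {
  X <- rbind(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), length(y) >= 1, min_leaf >= 1)
  grow <- function(idx) {
    yy <- y[idx]
    if (length(unique(yy)) == 1 || length(idx) < 2 * min_leaf) {
      return(list(leaf = TRUE, label = .majority(yy), n = length(idx)))
    }
    sp <- .tree_best_split(X[idx, , drop = FALSE], yy)
    if (is.null(sp)) {
      return(list(leaf = TRUE, label = .majority(yy), n = length(idx)))
    }
    left <- idx[X[idx, sp$feature] <= sp$threshold]
    right <- setdiff(idx, left)
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         gain = sp$gain, n = length(idx),
         left = grow(left), right = grow(right))
  }
  structure(list(root = grow(seq_along(y)), min_leaf = min_leaf,
                 classes = sort(unique(y)), n_features = ncol(X)),
            class = "ig_tree")
}

#' @export
predict.ig_tree <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("feature length mismatch with the trained tree")
  }
  one <- function(x) {
    node <- object$root
    while (!node$leaf) {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
    node$label
  }
  vapply(seq_len(nrow(newdata)), function(r) one(newdata[r, ]), "")
}

.tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(.tree_depth(node$left), .tree_depth(node$right))
}

#' @export
print.ig_tree <- function(x, ...) {
  n_leaves <- function(node) {
    if (node$leaf) return(1L)
    n_leaves(node$left) + n_leaves(node$right)
  }
  cat(sprintf("Information-gain decision tree: depth %d, %d leaves, classes: %s\n",
              .tree_depth(x$root), n_leaves(x$root),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
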