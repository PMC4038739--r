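# Soft-margin SVM with polynomial kernel, trained by sequential minimal
# optimization (SMO). This is the classifier core: a hand-rolled Platt-style
# dual solver, kept dependency-free so the trained model (support vectors,
# dual coefficients, bias) is fully transparent and serializable.
#
# Dual problem: maximize sum(alpha) - 1/2 sum_kl alpha_k alpha_l y_k y_l
# K(x_k, x_l) subject to 0 <= alpha <= C and sum(alpha * y) = 0. SMO
# optimizes one pair (alpha_i, alpha_j) analytically per step, keeping the
# equality constraint satisfied at all times.

#' Polynomial kernel
#'
#' `K(x, y) = (<x, y> + offset)^degree`. The homogeneous form
#' (`offset = 0`) is the default; `offset = 1` gives the inhomogeneous
#' variant common in SMO implementations.
#'
#' @param x,y numeric vectors of equal length, or matrices with vectors in
#'   rows (then the full Gram matrix is returned).
#' @param degree positive integer kernel exponent.
#' @param offset nonnegative additive constant inside the power.
#' @return scalar kernel value, or Gram matrix for matrix input.
#' @examples
#' poly_kernel(c(1, 2), c(3, 4), degree = 2)  # (3 + 8)^2 = 121
#' @export
poly_kernel <- function(x, y, degree = 1, offset = 0) {
  stopifnot(degree >= 1, degree == round(degree), offset >= 0)
  if (is.matrix(x) || is.matrix(y)) {
    x <- rbind(x); y <- rbind(y)
    if (ncol(x) != ncol(y)) stop("feature length mismatch")
    return((tcrossprod(x, y) + offset)^degree)
  }
  if (length(x) != length(y)) stop("feature length mismatch")
  (sum(x * y) + offset)^degree
}

#' SVM configuration
#'
#' @param degree polynomial kernel exponent p.
#' @param cost soft-margin penalty C.
#' @param offset kernel offset (0 = homogeneous, the default).
#' @param kkt_tol Karush-Kuhn-Tucker violation tolerance.
#' @param max_passes maximum sweeps over the training set without progress
#'   before stopping.
#' @param seed seed for the working-pair selection tie-breaks.
#' @return a list of class `svm_config`.
#' @export
svm_config <- function(degree = 1, cost = 1, offset = 0, kkt_tol = 1e-3,
                       max_passes = 200, seed = 1L) {
  stopifnot(degree >= 1, cost > 0, kkt_tol > 0, max_passes >= 1)
  structure(list(degree = degree, cost = cost, offset = offset,
                 kkt_tol = kkt_tol, max_passes = max_passes,
                 seed = as.integer(seed)),
            class = "svm_config")
}

# One SMO pair update. Returns updated (alpha, b, E) or NULL if no progress.
.smo_step <- function(i, j, alpha, b, E, K, y, C, eps = 1e-12) {
  if (i == j) return(NULL)
  ai <- alpha[i]; aj <- alpha[j]
  yi <- y[i]; yj <- y[j]
  if (yi != yj) {
    L <- max(0, aj - ai); H <- min(C, C + aj - ai)
  } else {
    L <- max(0, ai + aj - C); H <- min(C, ai + aj)
  }
  if (H - L < eps) return(NULL)
  eta <- K[i, i] + K[j, j] - 2 * K[i, j]
  if (eta <= eps) return(NULL)  # non-positive curvature: skip pair
  aj_new <- aj + yj * (E[i] - E[j]) / eta
  aj_new <- min(H, max(L, aj_new))
  if (abs(aj_new - aj) < eps * (aj_new + aj + eps)) return(NULL)
  ai_new <- ai + yi * yj * (aj - aj_new)
  # bias update (Platt): keep KKT for the updated pair
  b1 <- b - E[i] - yi * (ai_new - ai) * K[i, i] - yj * (aj_new - aj) * K[i, j]
  b2 <- b - E[j] - yi * (ai_new - ai) * K[i, j] - yj * (aj_new - aj) * K[j, j]
  b_new <- if (ai_new > eps && ai_new < C - eps) b1
  else if (aj_new > eps && aj_new < C - eps) b2
  else (b1 + b2) / 2
  dE <- yi * (ai_new - ai) * K[i, ] + yj * (aj_new - aj) * K[j, ] +
    (b_new - b)
  alpha[i] <- ai_new; alpha[j] <- aj_new
  list(alpha = alpha, b = b_new, E = E + dE)
}

#' Train a binary SVM by sequential minimal optimization
#'
#' Solves the soft-margin dual with a polynomial kernel. The first level of
#' `factor(y)` (or the first of `class_labels`) is the positive class,
#' coded +1.
#'
#' @param X numeric matrix, samples in rows.
#' @param y labels with exactly two distinct values (or +1/-1 numeric).
#' @param config an [svm_config()].
#' @param class_labels optional length-2 character vector fixing the
#'   (positive, negative) label order.
#' @return An object of class `smo_svm`: support vectors, dual
#'   coefficients (`alpha_k * y_k`, only `alpha_k > 0` kept), bias,
#'   config, class labels, and the full `alpha`/`y` for diagnostics.
#' @export
svm_train <- function(X, y, config = svm_config(), class_labels = NULL) {
  X <- rbind(X)
  if (is.null(class_labels)) {
    class_labels <- if (is.numeric(y) && all(y %in% c(-1, 1))) c("1", "-1")
    else levels(factor(y))
  }
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    yy <- y
  } else {
    if (!all(y %in% class_labels)) stop("labels outside class_labels")
    yy <- ifelse(y == class_labels[1], 1, -1)
  }
  if (length(unique(yy)) < 2) {
    stop("degenerate labels: both classes must be present")
  }
  n <- nrow(X)
  stopifnot(n == length(yy), n >= 2)
  C <- config$cost
  tol <- config$kkt_tol
  K <- poly_kernel(X, X, config$degree, config$offset)
  alpha <- numeric(n)
  b <- 0
  E <- -yy  # f(x) = 0 initially
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  sweeps <- 0L
  converged <- FALSE
  # a sweep that changes nothing means every point satisfies its KKT
  # condition within tol (or no pair admits progress): stop there
  while (sweeps < config$max_passes) {
    sweeps <- sweeps + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      r <- E[i] * yy[i]
      if ((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0)) {
        # second-choice heuristic: maximize |E_i - E_j|, random fallback
        j <- which.max(abs(E - E[i]))
        st <- .smo_step(i, j, alpha, b, E, K, yy, C)
        if (is.null(st)) {
          for (j in sample(n)) {
            st <- .smo_step(i, j, alpha, b, E, K, yy, C)
            if (!is.null(st)) break
          }
        }
        if (!is.null(st)) {
          alpha <- st$alpha; b <- st$b; E <- st$E
          changed <- changed + 1L
        }
      }
    }
    if (changed == 0L) { converged <- TRUE; break }
  }
  sv <- which(alpha > 1e-8)
  structure(list(support_vectors = X[sv, , drop = FALSE],
                 dual_coefs = alpha[sv] * yy[sv],
                 bias = b,
                 config = config,
                 class_labels = class_labels,
                 alpha = alpha, y = yy, n_train = n,
                 sweeps = sweeps, converged = converged),
            class = "smo_svm")
}

#' Decision values of a binary SVM
#'
#' `f(x) = sum_k alpha_k y_k K(s_k, x) + b`; the predicted label is the
#' positive class when `f(x) >= 0` (an exact 0 goes to the first class
#' label).
#'
#' @param object an [svm_train()] model.
#' @param newdata numeric matrix (or vector) of samples in rows.
#' @param type `"class"` for labels, `"decision"` for decision values.
#' @param ... ignored.
#' @return labels or decision values, per `type`.
#' @export
predict.smo_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  newdata <- rbind(newdata)
  if (ncol(newdata) != ncol(object$support_vectors)) {
    stop("feature length mismatch with the trained model")
  }
  Kx <- poly_kernel(newdata, object$support_vectors,
                    object$config$degree, object$config$offset)
  f <- drop(Kx %*% object$dual_coefs) + object$bias
  if (type == "decision") return(f)
  ifelse(f >= 0, object$class_labels[1], object$class_labels[2])
}

#' @export
print.smo_svm <- function(x, ...) {
  cat(sprintf(
    "Polynomial-kernel SVM (SMO): degree %d, C = %g, %d/%d support vectors\n",
    x$config$degree, x$config$cost, nrow(x$support_vectors), x$n_train))
  cat(sprintf("Classes: +1 = '%s', -1 = '%s'; bias = %.4g\n",
              x$class_labels[1], x$class_labels[2], x$bias))
  invisible(x)
}

#' Train a one-vs-one multiclass SVM
#'
#' One binary SVM per unordered class pair, trained on that pair's samples
#' only; prediction by majority vote, ties broken by the largest summed
#' absolute decision value, then by class order.
#'
#' @param X numeric matrix, samples in rows.
#' @param y labels with k >= 2 distinct values.
#' @param config an [svm_config()].
#' @return An object of class `ovo_svm` with one model per class pair.
#' @export
svm_train_multiclass <- function(X, y, config = svm_config()) {
  X <- rbind(X)
  classes <- levels(factor(y))
  if (length(classes) < 2) stop("need at least two classes")
  if (length(classes) == 2) {
    m <- svm_train(X, y, config, class_labels = classes)
    return(structure(list(models = list(m), classes = classes),
                     class = c("ovo_svm")))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    svm_train(X[sel, , drop = FALSE], y[sel], config, class_labels = pr)
  })
  structure(list(models = models, classes = classes), class = "ovo_svm")
}

#' @export
predict.ovo_svm <- function(object, newdata,
                            type = c("class", "votes"), ...) {
  type <- match.arg(type)
  newdata <- rbind(newdata)
  classes <- object$classes
  votes <- matrix(0, nrow(newdata), length(classes),
                  dimnames = list(NULL, classes))
  strength <- votes
  for (m in object$models) {
    f <- predict(m, newdata, type = "decision")
    winner <- ifelse(f >= 0, m$class_labels[1], m$class_labels[2])
    for (r in seq_along(f)) {
      votes[r, winner[r]] <- votes[r, winner[r]] + 1
      strength[r, winner[r]] <- strength[r, winner[r]] + abs(f[r])
    }
  }
  if (type == "votes") return(votes)
  apply_order <- function(r) {
    v <- votes[r, ]
    top <- which(v == max(v))
    if (length(top) > 1) {
      s <- strength[r, top]
      top <- top[s == max(s)]
    }
    classes[top[1]]  # remaining ties: class order
  }
  vapply(seq_len(nrow(newdata)), apply_order, "")
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf("One-vs-one SVM: %d classes (%s), %d pairwise model(s)\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$models)))
  invisible(x)
}
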