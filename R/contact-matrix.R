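# Contact matrices: symmetric nonnegative fragment-by-fragment interaction
# frequency (IF) matrices with an explicit measured/unmeasured mask.
# Unmeasured cells are NA in `values`, never silently zero.

#' Create a contact matrix
#'
#' A contact matrix holds pairwise interaction frequencies (IFs) between the
#' restriction fragments of a 5C design. Values are nonnegative and symmetric
#' where measured; cells that were not assayed (or failed) are `NA` and
#' tracked as unmeasured.
#'
#' @param values a square numeric matrix; `NA` marks unmeasured cells.
#' @param fragments optional [fragment_map()] with `nrow(values)` fragments.
#' @param symmetrize if `TRUE` (default), measured cell pairs whose values
#'   disagree by more than a relative 1e-6 are averaged with a warning;
#'   exact asymmetries below that tolerance are averaged silently. A cell
#'   measured on one side only is mirrored.
#' @return An object of class `contact_matrix`: a list with elements
#'   `values` (numeric matrix, `NA` = unmeasured) and `fragments`.
#' @examples
#' m <- contact_matrix(matrix(c(0, 5, 5, 0), 2))
#' measured(m)
#' @export
contact_matrix <- function(values, fragments = NULL, symmetrize = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    stop("contact matrix values must be nonnegative")
  }
  if (!is.null(fragments)) {
    stopifnot(inherits(fragments, "fragment_map"))
    if (nrow(fragments) != nrow(values)) {
      stop("fragment map size does not match matrix dimension")
    }
  }
  if (symmetrize) values <- .symmetrize(values)
  dimnames(values) <- NULL
  structure(list(values = values, fragments = fragments),
            class = "contact_matrix")
}

# Mirror one-sided measurements and average measured asymmetric pairs.
.symmetrize <- function(v) {
  tv <- t(v)
  both <- !is.na(v) & !is.na(tv)
  tol <- 1e-6 * pmax(abs(v), abs(tv), 1)
  bad <- both & abs(v - tv) > tol
  if (any(bad)) {
    warning(sprintf(
      "%d asymmetric measured cell pair(s) averaged during symmetrization",
      sum(bad) / 2L), call. = FALSE)
  }
  out <- ifelse(both, (v + tv) / 2, ifelse(is.na(v), tv, v))
  out
}

#' Measured-cell mask of a contact matrix
#' @param m a [contact_matrix()].
#' @return logical matrix, `TRUE` where the cell was measured.
#' @export
measured <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  !is.na(m$values)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

#' Matrix order (fragment count) of a contact matrix
#' @param m a [contact_matrix()].
#' @return integer.
#' @export
n_frag <- function(m) nrow(m$values)

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$values)
  nm <- sum(!is.na(x$values))
  cat(sprintf("Contact matrix: %d x %d fragments, %d/%d cells measured\n",
              n, n, nm, n * n))
  if (!is.null(x$fragments)) {
    cat(sprintf("Fragments: %s:%d-%d\n", x$fragments$chrom[1],
                min(x$fragments$start), max(x$fragments$end)))
  }
  k <- min(n, 5)
  print(round(x$values[seq_len(k), seq_len(k), drop = FALSE], 3))
  if (n > k) cat(sprintf("... (showing %d of %d rows)\n", k, n))
  invisible(x)
}

#' Heatmap of a contact matrix
#'
#' Draws the IF matrix with [graphics::image()], fragment 1 at the top-left
#' (the conventional 5C heatmap orientation). Difference maps (matrices with
#' negative entries are not valid contact matrices; pass a plain matrix via
#' `plot_if_map`) use a scale symmetric around zero.
#'
#' @param x a [contact_matrix()].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.contact_matrix <- function(x, main = "5C interaction frequencies", ...) {
  plot_if_map(x$values, main = main, ...)
  invisible(x)
}

#' Heatmap of an IF or IF-difference matrix
#'
#' @param v a square numeric matrix (may contain negatives, e.g. a class
#'   difference map, in which case the color scale is symmetric around 0).
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `v`, invisibly.
#' @export
plot_if_map <- function(v, main = "", ...) {
  n <- nrow(v)
  z <- t(v)[, n:1, drop = FALSE]
  if (any(v < 0, na.rm = TRUE)) {
    lim <- max(abs(v), na.rm = TRUE)
    cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
    graphics::image(seq_len(n), seq_len(n), z, zlim = c(-lim, lim),
                    col = cols, xlab = "fragment", ylab = "fragment",
                    main = main, axes = FALSE, ...)
  } else {
    cols <- grDevices::colorRampPalette(c("white", "yellow", "red"))(101)
    graphics::image(seq_len(n), seq_len(n), z, col = cols,
                    xlab = "fragment", ylab = "fragment", main = main,
                    axes = FALSE, ...)
  }
  graphics::axis(1, at = pretty(seq_len(n)))
  graphics::axis(2, at = pretty(seq_len(n)), labels = rev(pretty(seq_len(n))))
  graphics::box()
  invisible(v)
}
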