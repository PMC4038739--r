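# Interaction-frequency normalization.
#
# Raw 5C-on-array signal confounds the true contact frequency with (a) a
# per-array scale (how much DNA hybridized: "hybridization efficiency") and
# (b) per-primer efficiencies that act multiplicatively on every cell a
# fragment participates in. The correction is multiplicative:
#
#   raw[i,j] ~ e_i * e_j * s * IF[i,j]
#
# Per-fragment factors e are estimated by iterative proportional fitting
# (each fragment's factor updated from its row mean relative to the global
# mean, cells divided by f_i * f_j each round), then the whole matrix is
# scaled so the measured upper-triangle sum hits a fixed target. The result
# is invariant to the raw scale by construction.

#' Normalization configuration
#'
#' @param target_total sum of measured upper-triangle cells after scaling.
#'   IF units are relative, so any fixed constant is valid; default 1e6.
#' @param max_iter maximum balancing iterations.
#' @param tol convergence threshold: stop when every factor update is
#'   within `tol` of 1.
#' @param pseudocount nonnegative constant added to measured cells before
#'   balancing (0 by default; useful for sparse matrices).
#' @return a list of class `norm_config`.
#' @export
norm_config <- function(target_total = 1e6, max_iter = 200, tol = 1e-8,
                        pseudocount = 0) {
  stopifnot(target_total > 0, max_iter >= 1, tol > 0, pseudocount >= 0)
  structure(list(target_total = target_total, max_iter = max_iter,
                 tol = tol, pseudocount = pseudocount),
            class = "norm_config")
}

#' Scale a contact matrix to a fixed total
#'
#' Divides out the per-array scale by rescaling so that the sum of measured
#' upper-triangle cells (including the diagonal) equals `target_total`.
#'
#' @param raw a [contact_matrix()].
#' @param target_total positive target sum.
#' @return list with `matrix` (scaled [contact_matrix()]) and `array_scale`
#'   (the factor applied, `target_total / raw sum`).
#' @export
scale_to_total <- function(raw, target_total = 1e6) {
  stopifnot(inherits(raw, "contact_matrix"), target_total > 0)
  v <- raw$values
  ut <- upper.tri(v, diag = TRUE) & !is.na(v)
  total <- sum(v[ut])
  if (!any(ut) || total <= 0) {
    stop("degenerate input: no positive measured cell to scale")
  }
  s <- target_total / total
  out <- contact_matrix(v * s, fragments = raw$fragments, symmetrize = FALSE)
  list(matrix = out, array_scale = s)
}

#' Estimate per-primer efficiency factors
#'
#' Iterative proportional fitting: at each round the factor for fragment i
#' is updated by the arithmetic mean of the measured cells in row i divided
#' by the global measured mean, and every cell is divided by
#' `factor_i * factor_j`. Iteration stops when the largest factor update
#' deviates from 1 by less than `cfg$tol`, or at `cfg$max_iter` (flagged,
#' not an error). Returned factors are renormalized to geometric mean 1.
#'
#' Factors compose multiplicatively: planting efficiencies e on a matrix
#' multiplies the recovered factors by e (up to the global constant).
#'
#' @param raw a [contact_matrix()] in which every fragment has at least one
#'   measured positive contact.
#' @param cfg a [norm_config()].
#' @return list with `factors` (per-fragment, geometric mean 1),
#'   `iterations`, `converged`.
#' @export
estimate_primer_efficiencies <- function(raw, cfg = norm_config()) {
  stopifnot(inherits(raw, "contact_matrix"))
  v <- raw$values + ifelse(is.na(raw$values), 0, cfg$pseudocount)
  meas <- !is.na(v)
  row_n <- rowSums(meas)
  if (any(row_n == 0) || any(rowSums(v > 0, na.rm = TRUE) == 0)) {
    stop("every fragment needs at least one measured positive contact")
  }
  n <- nrow(v)
  f <- rep(1, n)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    gmean <- mean(v[meas])
    upd <- rowSums(v, na.rm = TRUE) / row_n / gmean
    upd <- sqrt(upd)  # each factor enters cells twice (row and column)
    v <- v / outer(upd, upd)
    f <- f * upd
    if (max(abs(upd - 1)) < cfg$tol) { converged <- TRUE; break }
  }
  f <- f / exp(mean(log(f)))
  list(factors = f, iterations = it, converged = converged)
}

#' Normalize one 5C sample
#'
#' Pipeline: optional pseudocount, per-primer efficiency correction
#' (divide cell (i, j) by `factor_i * factor_j`), then array scaling to a
#' fixed total. The unmeasured mask is preserved; unmeasured cells are
#' never imputed. The output is identical for `raw` and `c * raw`, any
#' c > 0.
#'
#' @param raw a [contact_matrix()].
#' @param cfg a [norm_config()].
#' @return An object of class `norm_result`: list with `normalized`
#'   ([contact_matrix()]), `array_scale`, `primer_efficiency`,
#'   `iterations`, `converged`.
#' @export
normalize_sample <- function(raw, cfg = norm_config()) {
  eff <- estimate_primer_efficiencies(raw, cfg)
  f <- eff$factors
  v <- (raw$values + ifelse(is.na(raw$values), 0, cfg$pseudocount)) /
    outer(f, f)
  corrected <- contact_matrix(v, fragments = raw$fragments,
                              symmetrize = FALSE)
  scaled <- scale_to_total(corrected, cfg$target_total)
  structure(list(normalized = scaled$matrix,
                 array_scale = scaled$array_scale,
                 primer_efficiency = f,
                 iterations = eff$iterations,
                 converged = eff$converged),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf(
    "5C normalization: %d fragments, array scale %.4g, %d iteration(s)%s\n",
    length(x$primer_efficiency), x$array_scale, x$iterations,
    if (x$converged) "" else " [did not converge]"))
  cat(sprintf("Primer efficiency range: %.3f - %.3f (geometric mean 1)\n",
              min(x$primer_efficiency), max(x$primer_efficiency)))
  invisible(x)
}

#' Normalize every sample of a panel
#'
#' @param panel a [sample_panel()].
#' @param cfg a [norm_config()].
#' @return a [sample_panel()] of normalized matrices; per-sample
#'   normalization metadata in attribute `norm_info`.
#' @export
normalize_panel <- function(panel, cfg = norm_config()) {
  res <- lapply(panel$matrices, normalize_sample, cfg = cfg)
  mats <- lapply(res, `[[`, "normalized")
  out <- sample_panel(mats, panel$meta, panel$fragments)
  attr(out, "norm_info") <- lapply(res, function(r)
    r[c("array_scale", "primer_efficiency", "iterations", "converged")])
  out
}
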