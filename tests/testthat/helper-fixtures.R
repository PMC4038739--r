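# Shared fixture builders: tiny panels and matrices generated in code.

# A fully measured symmetric n x n contact matrix from a seed.
random_contact_matrix <- function(n = 6, seed = 1, missing = 0) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v, diag = TRUE)] <- stats::runif(n * (n + 1) / 2, 0.5, 10)
  v <- v + t(v) - diag(diag(v))
  if (missing > 0) {
    idx <- which(upper.tri(v), arr.ind = TRUE)
    drop <- idx[sample(nrow(idx), missing), , drop = FALSE]
    v[drop] <- NA
    v[drop[, c(2, 1), drop = FALSE]] <- NA
  }
  contact_matrix(v, symmetrize = FALSE)
}

# A tiny labeled panel: per-class constant matrices plus N(0, sd) noise on
# the log scale, optional planted fold change at given pairs for class 1.
tiny_panel <- function(n_frag = 6, n_per_class = 4, sd = 0.1,
                       planted = NULL, fold = 3, seed = 1) {
  set.seed(seed)
  base <- matrix(5, n_frag, n_frag)
  mk <- function(cl, k) {
    v <- base * exp(matrix(stats::rnorm(n_frag^2, 0, sd), n_frag))
    v <- (v + t(v)) / 2
    if (cl == "fusion" && !is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        i <- planted[r, 1]; j <- planted[r, 2]
        v[i, j] <- v[i, j] * fold; v[j, i] <- v[i, j]
      }
    }
    contact_matrix(v, symmetrize = FALSE)
  }
  cls <- rep(c("fusion", "wt"), each = n_per_class)
  mats <- lapply(seq_along(cls), function(k) mk(cls[k], k))
  ids <- sprintf("s%02d", seq_along(cls))
  names(mats) <- ids
  meta <- data.frame(sample_id = ids, mll_status = cls,
                     subtype = ifelse(cls == "fusion", "AF9", "none"),
                     leukemia_type = "AML", stringsAsFactors = FALSE)
  sample_panel(mats, meta)
}

# Separable two-class Gaussian data in d dimensions.
separable_blobs <- function(n_per = 8, d = 3, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d), ncol = d),
             matrix(stats::rnorm(n_per * d, mean = gap), ncol = d))
  list(X = X, y = rep(c("neg", "pos"), each = n_per))
}
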