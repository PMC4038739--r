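# Synthetic 5C panel generator.
#
# Emulates a 5C-on-array study of a ~40-fragment restriction map: a
# power-law distance-decay baseline, class-specific planted contact
# enrichments (fold changes at chosen fragment pairs), per-primer
# efficiency biases, a per-array scale factor, and multiplicative
# lognormal measurement noise:
#
#   raw[i,j] = true[i,j] * e_i * e_j * s * exp(N(0, noise_sigma^2))
#
# with e_i ~ lognormal(0, efficiency_sigma^2) per sample and
# s ~ Uniform(array_scale_range). Ground truth (true matrices,
# efficiencies, scales) is returned for recovery tests.

#' Simulation design
#'
#' @param n_fragments number of restriction fragments.
#' @param decay_exponent power-law distance-decay exponent alpha:
#'   baseline IF between fragments i and j is `base_if * |i-j|^-alpha`.
#' @param base_if baseline IF at distance 1.
#' @param planted_effects data frame with columns `i`, `j`, `fold_change`,
#'   `class` — pairs enriched (fold > 1) or depleted in samples whose MLL
#'   status or subtype equals `class`.
#' @param class_sizes named integer vector over composite labels
#'   `status:subtype` (e.g. `fusion:AF9`), or plain statuses.
#' @param noise_sigma lognormal measurement noise sd (log scale).
#' @param efficiency_sigma lognormal sd of per-primer efficiencies.
#' @param array_scale_range length-2 range of the uniform per-array scale.
#' @param diag_if IF assigned to the self-ligation diagonal.
#' @param seed integer seed; the whole panel is reproducible from it.
#' @return a list of class `sim_design`.
#' @seealso [hoxa_design()] for the default leukemia-panel preset.
#' @export
sim_design <- function(n_fragments = 40, decay_exponent = 1, base_if = 100,
                       planted_effects = NULL,
                       class_sizes = c(`fusion:AF9` = 10, `fusion:ENL` = 10,
                                       `wt:none` = 10),
                       noise_sigma = 0.3, efficiency_sigma = 0.2,
                       array_scale_range = c(0.5, 2), diag_if = NULL,
                       seed = 1L) {
  stopifnot(n_fragments >= 2, decay_exponent > 0, base_if > 0,
            noise_sigma >= 0, efficiency_sigma >= 0,
            length(array_scale_range) == 2,
            array_scale_range[1] <= array_scale_range[2],
            array_scale_range[1] > 0, all(class_sizes >= 1))
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(i = integer(), j = integer(),
                                  fold_change = numeric(),
                                  class = character())
  }
  if (nrow(planted_effects)) {
    stopifnot(all(planted_effects$i >= 1),
              all(planted_effects$j >= 1),
              all(planted_effects$i <= n_fragments),
              all(planted_effects$j <= n_fragments),
              all(planted_effects$fold_change > 0))
  }
  if (is.null(diag_if)) diag_if <- 2 * base_if
  structure(list(n_fragments = n_fragments,
                 decay_exponent = decay_exponent, base_if = base_if,
                 planted_effects = planted_effects,
                 class_sizes = class_sizes, noise_sigma = noise_sigma,
                 efficiency_sigma = efficiency_sigma,
                 array_scale_range = array_scale_range, diag_if = diag_if,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Leukemia-panel simulation preset
#'
#' The default study design: 30 samples over a 40-fragment map — 20
#' expressing an MLL fusion (10 MLL-AF9, 10 MLL-ENL) and 10 with only the
#' wild-type protein. The planted contact geography mirrors the biology of
#' the HOXA cluster in MLL leukemias: fusion samples gain contacts between
#' the HOXA11 region (fragments 26-27) and the rest of the cluster, while
#' wild-type samples gain long-range contacts between the region downstream
#' of HOXA13 (fragments 31-35) and the cluster 3' end, plus the neighbor
#' pairs 14-15 and 32-33. The two fusion subtypes additionally differ on
#' disjoint pair sets distributed throughout the cluster, stronger in
#' MLL-AF9.
#'
#' @param fold_change planted enrichment fold.
#' @param noise_sigma lognormal measurement noise sd.
#' @param seed integer seed.
#' @param subtype_effects include the AF9/ENL-distinguishing planted pairs.
#' @param ... further arguments passed to [sim_design()].
#' @return a [sim_design()].
#' @export
hoxa_design <- function(fold_change = 2.5, noise_sigma = 0.3, seed = 1L,
                        subtype_effects = TRUE, ...) {
  fusion_pairs <- rbind(
    expand.grid(i = 26:27, j = c(5, 10, 16, 21, 33, 38)))
  wt_pairs <- rbind(
    expand.grid(i = 31:35, j = c(2, 4, 6, 8, 10)),
    data.frame(i = 14, j = 15), data.frame(i = 32, j = 33))
  eff <- rbind(
    data.frame(i = fusion_pairs$i, j = fusion_pairs$j,
               fold_change = fold_change, class = "fusion"),
    data.frame(i = wt_pairs$i, j = wt_pairs$j,
               fold_change = fold_change, class = "wt"))
  if (subtype_effects) {
    # 20 subtype-distinguishing contacts distributed throughout the
    # cluster, generally stronger in MLL-AF9; the neighbor pairs 14-15 and
    # 32-33 are instead stronger in MLL-ENL (they also mark wt samples)
    af9_pairs <- data.frame(
      i = c(1, 3, 5, 7, 9, 11, 13, 16, 18, 20, 22, 24, 26, 28, 30, 33, 36,
            38),
      j = c(12, 17, 23, 29, 31, 25, 34, 37, 39, 40, 35, 32, 39, 36, 40, 39,
            40, 40))
    enl_pairs <- data.frame(i = c(14, 32), j = c(15, 33))
    eff <- rbind(eff,
                 data.frame(i = af9_pairs$i, j = af9_pairs$j,
                            fold_change = fold_change, class = "AF9"),
                 data.frame(i = enl_pairs$i, j = enl_pairs$j,
                            fold_change = fold_change, class = "ENL"))
  }
  sim_design(n_fragments = 40, planted_effects = eff,
             noise_sigma = noise_sigma, seed = seed, ...)
}

#' Distance-decay baseline expected IF matrix
#'
#' `expected[i, j] = base_if * |i - j|^-alpha` for i != j; the diagonal is
#' set to `diag_if` (self-ligation signal, by default twice `base_if`).
#'
#' @param n_fragments fragment count (>= 2).
#' @param decay_exponent positive decay exponent alpha.
#' @param base_if baseline IF at distance 1.
#' @param diag_if diagonal value.
#' @return a [contact_matrix()].
#' @export
baseline_expected <- function(n_fragments, decay_exponent = 1,
                              base_if = 100, diag_if = 2 * base_if) {
  if (n_fragments < 2) stop("need at least 2 fragments")
  if (decay_exponent <= 0) stop("decay exponent must be positive")
  d <- abs(outer(seq_len(n_fragments), seq_len(n_fragments), `-`))
  v <- base_if * ifelse(d == 0, NA, d)^(-decay_exponent)
  diag(v) <- diag_if
  contact_matrix(v, fragments = .synthetic_fragment_map(n_fragments),
                 symmetrize = FALSE)
}

# Evenly spaced synthetic BglII-like fragments (~2.5 kb) on one chromosome.
.synthetic_fragment_map <- function(n) {
  w <- 2500L
  fragment_map(chrom = "chr7",
               start = 27100000L + (seq_len(n) - 1L) * w,
               end = 27100000L + seq_len(n) * w - 1L,
               orientation = rep(c("FOR", "REV"), length.out = n))
}

# True IF matrix for one class label pair (status, subtype): baseline with
# planted fold changes applied where the effect class matches either label.
.true_matrix <- function(design, status, subtype) {
  base <- baseline_expected(design$n_fragments, design$decay_exponent,
                            design$base_if, design$diag_if)
  v <- base$values
  pe <- design$planted_effects
  hit <- pe$class == status | pe$class == subtype
  if (any(hit)) {
    for (k in which(hit)) {
      v[pe$i[k], pe$j[k]] <- v[pe$i[k], pe$j[k]] * pe$fold_change[k]
      v[pe$j[k], pe$i[k]] <- v[pe$i[k], pe$j[k]]
    }
  }
  v
}

#' Simulate one raw 5C sample
#'
#' @param design a [sim_design()].
#' @param status MLL status label (`fusion` or `wt`).
#' @param subtype fusion subtype label (or `none`).
#' @param seed integer seed for this sample's draws.
#' @return list with `raw` (a [contact_matrix()]) and `truth` (list:
#'   `true_if` matrix, `efficiencies`, `array_scale`, `status`, `subtype`).
#' @export
simulate_sample <- function(design, status, subtype = "none", seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  true_if <- .true_matrix(design, status, subtype)
  n <- design$n_fragments
  set.seed(seed)
  e <- exp(stats::rnorm(n, 0, design$efficiency_sigma))
  s <- stats::runif(1, design$array_scale_range[1],
                    design$array_scale_range[2])
  noise <- matrix(0, n, n)
  noise[upper.tri(noise, diag = TRUE)] <-
    stats::rnorm(n * (n + 1) / 2, 0, design$noise_sigma)
  noise <- noise + t(noise) - diag(diag(noise))
  raw <- true_if * outer(e, e) * s * exp(noise)
  list(raw = contact_matrix(raw,
                            fragments = .synthetic_fragment_map(n),
                            symmetrize = FALSE),
       truth = list(true_if = true_if, efficiencies = e, array_scale = s,
                    status = status, subtype = subtype))
}

#' Simulate a labeled 5C panel
#'
#' Draws `class_sizes` samples per composite class. A single design seed
#' governs the whole panel: per-sample seeds are derived deterministically
#' from it, so identical designs give bit-identical panels.
#'
#' @param design a [sim_design()].
#' @param seed optional override of `design$seed`.
#' @param id_prefix sample-id prefix; the default embeds the seed so
#'   panels simulated under different seeds have disjoint sample ids
#'   (required by [run_denovo()]).
#' @return list with `panel` (a [sample_panel()] of raw matrices) and
#'   `truth` (per-sample ground-truth list).
#' @export
simulate_panel <- function(design, seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) design$seed <- as.integer(seed)
  if (is.null(id_prefix)) id_prefix <- sprintf("s%d", design$seed)
  labels <- strsplit(names(design$class_sizes), ":", fixed = TRUE)
  status <- rep(vapply(labels, `[`, "", 1), design$class_sizes)
  subtype <- rep(vapply(labels, function(x)
    if (length(x) > 1) x[2] else "none", ""), design$class_sizes)
  n_samp <- length(status)
  set.seed(design$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samp)
  sims <- lapply(seq_len(n_samp), function(k)
    simulate_sample(design, status[k], subtype[k], seed = sample_seeds[k]))
  ids <- sprintf("%s_%s_%s_%02d", id_prefix, status, subtype,
                 seq_len(n_samp))
  mats <- lapply(sims, `[[`, "raw")
  names(mats) <- ids
  meta <- data.frame(sample_id = ids, mll_status = status,
                     subtype = subtype,
                     leukemia_type = ifelse(subtype == "AF9", "AML",
                                            ifelse(subtype == "ENL", "ALL",
                                                   "AML")),
                     stringsAsFactors = FALSE)
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  list(panel = sample_panel(mats, meta,
                            .synthetic_fragment_map(design$n_fragments)),
       truth = truth)
}
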