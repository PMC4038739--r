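---
title: "Methods: classifying disease samples from 5C chromatin signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying disease samples from 5C chromatin signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromsig)
```

# The problem

Chromosome conformation capture carbon copy (5C) measures the interaction
frequency (IF) between pairs of restriction fragments in a genomic region.
A sample's 5C profile over a disease-relevant locus — here modeled on the
HOXA gene cluster, whose spatial organization differs between leukemias
driven by MLL fusion proteins and cells carrying only wild-type MLL — can
be treated as a *chromatin conformation signature*: a feature vector on
which a classifier separates disease classes and from which the
discriminatory fragment-fragment contacts can be read off.

This package implements that pipeline end to end: raw IF matrices are
normalized for per-primer efficiency and per-array scale, vectorized over
the upper triangle of the fragment-pair grid, classified with a
polynomial-kernel support vector machine (SVM) under leave-one-out
cross-validation (LOOCV), and mined for informative contacts with
supervised discretization, information gain, and two-sample t-tests. A
synthetic panel generator with planted, class-specific contacts provides
ground truth for validating every stage.

# Data model

A `contact_matrix` is a symmetric n-fragment IF matrix in which `NA`
marks unmeasured primer pairs (5C only probes forward-against-reverse
primers, and arrays drop probes); unmeasured cells are carried through
normalization untouched and handled at the feature stage. Matrices read
and write a my5C-style tab-delimited dialect whose row/column headers
encode `NAME|ASSEMBLY|chrom:start-end`; fragment maps round-trip through
BED (0-based half-open on disk, 1-based inclusive in memory). A
`sample_panel` bundles matrices with two-level labels: MLL status
(`fusion` / `wt`) and fusion subtype (`AF9`, `ENL`, ...).

# Normalization

Two nuisance factors dominate raw 5C counts: each primer's ligation and
hybridization efficiency, and an overall per-array scale. We model the
raw count as `raw[i,j] = true[i,j] * e_i * e_j * s` and estimate the
`e_i` by iterative proportional fitting on the measured cells: at each
iteration every row's mean over measured entries is compared with the
global mean and the cell values are divided by
`sqrt(rowmean_i / globalmean) * sqrt(rowmean_j / globalmean)`. The square
root damps the update so that alternating row/column over-corrections
cannot oscillate; iteration stops when the largest relative update falls
below `tol` (default `1e-8`, `max_iter = 200`). The accumulated factors
are reported normalized to geometric mean 1, which fixes the scale
indeterminacy of the multiplicative model. Finally the matrix is scaled
so that the measured upper triangle (diagonal included) sums to
`target_total` (default `1e6`), making profiles comparable across
arrays.

Two properties are guaranteed and tested: exact invariance under
`raw -> c * raw` for any `c > 0`, and idempotence (normalizing a
normalized matrix is a no-op up to the convergence tolerance). Planted
efficiencies are recovered on synthetic matrices with log-log Pearson
correlation above 0.999 noise-free; note that distance-decay structure in
`true[i,j]` itself contributes to row means, so exact recovery is only
identifiable up to that structure — the recovery checks therefore use a
flat truth matrix, and on realistic decaying matrices the factors absorb
a smooth distance component, which cancels between samples sharing the
design.

# Feature construction

A `feature_index` maps the upper triangle (diagonal excluded by default —
self-ligation signal is technical) to a fixed feature order. Two missing
policies exist: `intersect` keeps only pairs measured in every sample
(the default; no imputation ever enters the classifier), and
`impute_row_mean` fills a missing cell with the training panel's mean for
that pair (needed when projecting an external test panel onto a training
index). Features are standardized per column (training mean and standard
deviation; zero deviations map to 1) before the SVM.

# Classifier

The SVM is a standard soft-margin machine with the homogeneous polynomial
kernel `K(x, y) = <x, y>^p` (an `offset` option gives the inhomogeneous
form). It is trained by sequential minimal optimization: pairs of dual
variables are optimized in closed form with box clipping, errors are
cached, the second index is chosen to maximize the error gap with a
random fallback, and training stops at the first full sweep that changes
nothing — which certifies the Karush-Kuhn-Tucker conditions within
`kkt_tol` (default `1e-3`; `max_passes = 200` caps the sweep count).
Defaults `p = 1`, `C = 1` are deliberately conservative: on standardized
5C features a linear decision function is already strong and its weights
are interpretable per fragment pair (`coef()`); the homogeneous `p = 2`
kernel is what the XOR correctness check exercises. Multiclass problems
use one-vs-one voting with ties broken by summed decision magnitudes. An
information-gain decision tree (greedy midpoint splits with a one-step
lookahead so parity-structured data such as XOR is still split) is
provided as a simple alternative classifier.

Evaluation is leave-one-out: the feature index is built once on the full
panel (a label-free operation on the measurement masks), while
imputation means, standardization, and the model itself are recomputed
from the n−1 training samples in every fold. Reported metrics are
accuracy and the Matthews correlation coefficient, with the convention
MCC = 0 whenever a denominator factor vanishes.

# Discriminatory contacts

Each feature is scored two ways. Information gain is computed over a
Fayyad-Irani supervised discretization: recursive binary cuts at class
boundary midpoints, each accepted only if the gain exceeds the minimum
description length criterion
`log2(N-1)/N + [log2(3^k - 2) - k*H + k1*H1 + k2*H2]/N`; features that
earn no cut score zero. Independently, a two-sided two-sample t-test
(Welch by default) compares class means per feature; `alpha = 0.01` with
no multiple-testing correction is the default filter, with an optional
Benjamini-Hochberg mode. An *informative contact* passes the t-test and
has positive gain; contacts are ranked by gain. Class-averaged and
difference IF maps support visual inspection.

# The simulator

`simulate_panel()` draws labeled panels from a generative model chosen to
exercise exactly the failure modes the pipeline must survive:

* a power-law distance-decay baseline `base_if * |i - j|^-alpha`
  (defaults `base_if = 100`, `alpha = 1`, diagonal `2 * base_if`), the
  dominant structure of real contact maps;
* planted class-specific contacts: chosen fragment pairs multiplied by
  `fold_change` (default 2.5) in samples of a matching status or
  subtype;
* per-sample primer efficiencies `e_i ~ lognormal(0, 0.2^2)`, an array
  scale `s ~ Uniform(0.5, 2)`, and multiplicative lognormal measurement
  noise with `noise_sigma = 0.3`.

`hoxa_design()` is the default 40-fragment, 30-sample study layout (10
MLL-AF9, 10 MLL-ENL, 10 wild-type): fusion samples gain contacts between
fragments 26-27 and six positions across the cluster; wild-type samples
gain contacts between fragments 31-35 and the cluster 3' end plus the
neighbor pairs 14-15 and 32-33; the subtypes differ on 20 further pairs,
18 stronger in MLL-AF9 and the two neighbor pairs stronger in MLL-ENL.
The problem sizes (40 fragments, 20 + 10 samples, 780 pairwise features)
are this package's own choice of a desk-scale design that keeps LOOCV
runs under a second while leaving the subtype task measurably harder
than the type task. Ground truth (true matrices, efficiencies, scales)
is returned for recovery tests.

What the simulator deliberately does **not** emulate: read-count
(Poisson/negative-binomial) noise — counts are treated as continuous
array intensities; copy-number variation; domain/compartment structure
beyond monotone decay; inter-chromosomal contacts; primer-specific
missingness patterns (missingness is user-injected, not generated); and
any coupling between the two nuisance factors and the class label.

# Numerical choices

Seeds fully determine every simulation (per-sample seeds are drawn from
the design seed; `set.seed` state is saved and restored around internal
use). Entropies are computed in bits with the `0 log 0 = 0` convention.
Degenerate t-test columns follow a fixed convention: zero variance in
both groups yields `t = 0, p = 1` at equal means and `p = 0` with a
warning at unequal means. The SMO convergence tolerance trades exactness
for speed; permutation invariance of the decision function holds to
`1e-6` at `kkt_tol = 1e-7`. JSON model serialization flattens support
vectors row-major with explicit dimensions so a restored model predicts
bit-identically.

# Open design decisions and limitations

* Whether informative contacts should intersect the t-test and
  information-gain criteria or rely on the t-test alone is left open;
  both columns are reported so either convention can be applied.
* No multiple-testing correction is applied by default; at
  `alpha = 0.01` over 780 features roughly 8 false positives are
  expected under the null, which the calibration tests quantify.
* LOOCV with feature standardization recomputed per fold is unbiased but
  expensive at scale; no speed-up approximations are attempted.
* The SVM has no probability calibration; decision values are reported
  raw.
* The normalization assumes a purely multiplicative bias model;
  fragment-length or GC effects are not modeled.
* With unbalanced groups and skewed (lognormal) noise the Welch test's
  finite-sample size can drift slightly above nominal; calibration
  checks use balanced null panels, and users testing unbalanced designs
  at strict thresholds should prefer log-transformed IFs.

This vignette states no empirical result beyond what the package's test
suite and the `scripts/acceptance.R` script recompute.
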