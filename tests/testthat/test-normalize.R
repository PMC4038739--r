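# IF normalization: array scaling, primer-efficiency balancing, and the
# full per-sample pipeline.

test_that("scale_to_total hits the target and preserves proportions", {
  v <- matrix(c(10, 15, 15, 10), 2)   # measured upper triangle sums to 35
  m <- contact_matrix(v)
  out <- scale_to_total(m, 70)
  expect_equal(sum(out$matrix$values[upper.tri(v, diag = TRUE)]), 70)
  expect_equal(out$array_scale, 2)
  expect_equal(out$matrix$values, v * 2)

  # already at target: identity
  out2 <- scale_to_total(out$matrix, 70)
  expect_equal(out2$array_scale, 1)

  for (seed in 1:5) {
    m <- random_contact_matrix(8, seed)
    out <- scale_to_total(m, 1e6)
    ut <- upper.tri(m$values, diag = TRUE) & measured(m)
    expect_equal(sum(out$matrix$values[ut]), 1e6, tolerance = 1e-9)
  }
  expect_error(scale_to_total(contact_matrix(matrix(0, 2, 2)), 10),
               "degenerate")
})

test_that("a balanced matrix is a fixed point of efficiency estimation", {
  n <- 8
  v <- matrix(3, n, n)   # all row means equal: already balanced
  m <- contact_matrix(v, symmetrize = FALSE)
  eff <- estimate_primer_efficiencies(m, norm_config(tol = 1e-10))
  expect_true(eff$converged)
  expect_equal(eff$factors, rep(1, n), tolerance = 1e-9)
})

test_that("planted efficiencies on a balanced truth are recovered exactly", {
  n <- 12
  set.seed(5)
  e <- exp(rnorm(n, 0, 0.4))
  truth <- matrix(4, n, n)
  raw <- contact_matrix(truth * outer(e, e), symmetrize = FALSE)
  eff <- estimate_primer_efficiencies(raw, norm_config(tol = 1e-12,
                                                       max_iter = 500))
  expect_true(eff$converged)
  e_norm <- e / exp(mean(log(e)))   # comparable up to a global constant
  expect_equal(eff$factors, e_norm, tolerance = 1e-6)
})

test_that("estimated factors compose multiplicatively and equivary under permutation", {
  base <- baseline_expected(10, decay_exponent = 1, base_if = 100)
  cfg <- norm_config(tol = 1e-12, max_iter = 1000)
  f_base <- estimate_primer_efficiencies(base, cfg)$factors
  set.seed(11)
  e <- exp(rnorm(10, 0, 0.3))
  raw <- contact_matrix(base$values * outer(e, e), symmetrize = FALSE)
  f_raw <- estimate_primer_efficiencies(raw, cfg)$factors
  # factors(e * T) = e * factors(T) up to the geometric-mean constant
  expect_equal(f_raw, f_base * e / exp(mean(log(e))), tolerance = 1e-6)

  perm <- sample(10)
  raw_p <- contact_matrix(raw$values[perm, perm], symmetrize = FALSE)
  f_p <- estimate_primer_efficiencies(raw_p, cfg)$factors
  expect_equal(f_p, f_raw[perm], tolerance = 1e-9)
})

test_that("normalization is scale invariant and idempotent", {
  raw <- random_contact_matrix(10, seed = 2)
  cfg <- norm_config(tol = 1e-10)
  a <- normalize_sample(raw, cfg)
  b <- normalize_sample(contact_matrix(raw$values * 37.5,
                                       symmetrize = FALSE), cfg)
  expect_equal(a$normalized$values, b$normalized$values, tolerance = 1e-9)
  expect_equal(b$array_scale, a$array_scale / 37.5, tolerance = 1e-9)

  # renormalizing a normalized matrix moves no cell beyond tolerance
  c2 <- normalize_sample(a$normalized, cfg)
  expect_equal(c2$normalized$values, a$normalized$values, tolerance = 1e-6)

  # uniform input stays uniform
  u <- normalize_sample(contact_matrix(matrix(2, 6, 6)), cfg)
  offdiag <- u$normalized$values[upper.tri(u$normalized$values)]
  expect_true(max(abs(offdiag - offdiag[1])) < 1e-9)
})

test_that("simulated raw with known efficiencies normalizes back to truth", {
  d <- sim_design(n_fragments = 12, noise_sigma = 0, efficiency_sigma = 0.3,
                  seed = 4)
  s <- simulate_sample(d, "wt", seed = 21)
  res <- normalize_sample(s$raw, norm_config(tol = 1e-12, max_iter = 1000))
  # normalized must be proportional to truth after removing the truth's own
  # structural balance (shared by both sides of the comparison)
  tru <- normalize_sample(contact_matrix(s$truth$true_if,
                                         symmetrize = FALSE),
                          norm_config(tol = 1e-12, max_iter = 1000))
  expect_equal(res$normalized$values, tru$normalized$values,
               tolerance = 1e-6)
  # unmeasured mask preserved
  raw2 <- s$raw
  raw2$values[1, 5] <- raw2$values[5, 1] <- NA
  res2 <- normalize_sample(raw2, norm_config())
  expect_false(measured(res2$normalized)[1, 5])
})
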