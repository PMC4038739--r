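# Synthetic 5C panel generator: baseline decay, planted effects, noise
# model, determinism.

test_that("baseline decay matches its closed form", {
  b <- baseline_expected(10, decay_exponent = 1, base_if = 100)
  expect_equal(b$values[1, 2], 100)
  expect_equal(b$values[1, 3], 50)
  # brute-force loop oracle
  for (i in 1:10) for (j in 1:10) {
    if (i != j) expect_equal(b$values[i, j], 100 * abs(i - j)^-1)
  }
  # symmetric, strictly decreasing with distance
  expect_equal(b$values, t(b$values))
  d1 <- b$values[1, 2:9]; d2 <- b$values[1, 3:10]
  expect_true(all(d1 > d2))

  b2 <- baseline_expected(6, decay_exponent = 1.5, base_if = 10)
  expect_equal(b2$values[2, 5], 10 * 3^-1.5)
  expect_error(baseline_expected(6, decay_exponent = 0), "positive")
  expect_error(baseline_expected(1), "at least 2")
})

test_that("noise-free simulation returns the planted truth exactly", {
  d <- sim_design(n_fragments = 8, noise_sigma = 0, efficiency_sigma = 0,
                  array_scale_range = c(1, 1),
                  planted_effects = data.frame(i = 2, j = 6,
                                               fold_change = 3,
                                               class = "fusion"))
  s_f <- simulate_sample(d, "fusion", seed = 1)
  s_w <- simulate_sample(d, "wt", seed = 1)
  expect_equal(s_f$raw$values, s_f$truth$true_if)
  base <- baseline_expected(8, d$decay_exponent, d$base_if, d$diag_if)
  expect_equal(s_f$truth$true_if[2, 6], 3 * base$values[2, 6])
  expect_equal(s_f$truth$true_if[6, 2], 3 * base$values[2, 6])
  expect_equal(s_w$truth$true_if, base$values)  # effect only in its class
})

test_that("simulation is bit-identical under one seed, distinct under another", {
  d <- hoxa_design(seed = 5)
  d$class_sizes <- c(`fusion:AF9` = 2, `wt:none` = 2)
  p1 <- simulate_panel(d)
  p2 <- simulate_panel(d)
  expect_identical(p1$panel$matrices[[1]]$values,
                   p2$panel$matrices[[1]]$values)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_panel(d, seed = 6)
  expect_false(identical(p1$panel$matrices[[1]]$values,
                         p3$panel$matrices[[1]]$values))
})

test_that("panel composition follows the class sizes", {
  sim <- simulate_panel(hoxa_design(seed = 2))
  tab <- table(sim$panel$meta$mll_status)
  expect_equal(as.integer(tab["fusion"]), 20L)
  expect_equal(as.integer(tab["wt"]), 10L)
  expect_equal(as.integer(table(sim$panel$meta$subtype)[c("AF9", "ENL")]),
               c(10L, 10L))
  expect_equal(n_frag(sim$panel$matrices[[1]]), 40)
})

test_that("replicate means converge to truth times the noise expectation", {
  d <- sim_design(n_fragments = 6, noise_sigma = 0.2, efficiency_sigma = 0.1,
                  array_scale_range = c(0.8, 1.25), seed = 3)
  base <- baseline_expected(6, d$decay_exponent, d$base_if, d$diag_if)
  reps <- lapply(1:200, function(k) simulate_sample(d, "wt", seed = k))
  avg <- Reduce(`+`, lapply(reps, function(s) s$raw$values)) / 200
  # E[raw] = true * E[e_i e_j] * E[s] * exp(sigma^2 / 2); with independent
  # lognormal efficiencies E[e_i e_j] = exp(eff_sigma^2) off the diagonal
  es <- mean(vapply(reps, function(s) s$truth$array_scale, 0))
  expect_factor <- exp(d$efficiency_sigma^2) * es * exp(d$noise_sigma^2 / 2)
  off <- upper.tri(avg)
  ratio <- avg[off] / (base$values[off] * expect_factor)
  expect_true(all(abs(ratio - 1) < 0.15))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("class-mean fold at a planted cell recovers the design fold", {
  d <- sim_design(n_fragments = 10, noise_sigma = 0.2,
                  efficiency_sigma = 0, array_scale_range = c(1, 1),
                  planted_effects = data.frame(i = 3, j = 8,
                                               fold_change = 2.5,
                                               class = "fusion"),
                  class_sizes = c(`fusion:AF9` = 15, `wt:none` = 15),
                  seed = 8)
  # a single 30-sample panel has ~7% Monte-Carlo error on the ratio of
  # class means; average over replicate panels to test the recovery itself
  ratios <- vapply(1:5, function(k) {
    sim <- simulate_panel(d, seed = 7 + k)
    y <- sim$panel$meta$mll_status
    cell <- vapply(sim$panel$matrices, function(m) m$values[3, 8], 0)
    mean(cell[y == "fusion"]) / mean(cell[y == "wt"])
  }, 0)
  expect_lt(abs(mean(ratios) - 2.5) / 2.5, 0.1)
})

test_that("null designs produce uniform t-test p-values at any cell", {
  d <- sim_design(n_fragments = 6, noise_sigma = 0.3, efficiency_sigma = 0,
                  array_scale_range = c(1, 1),
                  class_sizes = c(`fusion:AF9` = 10, `wt:none` = 10))
  ps <- vapply(1:60, function(k) {
    sim <- simulate_panel(d, seed = 1000 + k)
    y <- sim$panel$meta$mll_status
    cell <- log(vapply(sim$panel$matrices, function(m) m$values[2, 5], 0))
    stats::t.test(cell[y == "fusion"], cell[y == "wt"])$p.value
  }, 0)
  # Kolmogorov-Smirnov against uniform: should not reject at 0.1%
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("panel directories round-trip through write_panel/read_panel", {
  d <- hoxa_design(seed = 9)
  d$class_sizes <- c(`fusion:AF9` = 2, `wt:none` = 2)
  sim <- simulate_panel(d)
  dir <- withr::local_tempdir()
  csv <- write_panel(sim$panel, dir, dialect = "my5c")
  back <- read_panel(csv, dialect = "my5c")
  expect_equal(length(back), 4)
  expect_equal(back$meta$mll_status, sim$panel$meta$mll_status)
  expect_equal(back$matrices[[1]]$values, sim$panel$matrices[[1]]$values,
               tolerance = 1e-9)
})
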