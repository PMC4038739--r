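# Class-mean maps, per-contact t-tests, and informative-contact ranking.

test_that("class mean maps average per cell and difference subtracts", {
  # two identical samples per class: mean equals the sample, difference is
  # the class gap
  v_f <- matrix(4, 5, 5); v_w <- matrix(1, 5, 5)
  mats <- list(s1 = contact_matrix(v_f), s2 = contact_matrix(v_f),
               s3 = contact_matrix(v_w), s4 = contact_matrix(v_w))
  meta <- data.frame(sample_id = names(mats),
                     mll_status = c("fusion", "fusion", "wt", "wt"),
                     subtype = "none", leukemia_type = "AML")
  panel <- sample_panel(mats, meta)
  maps <- class_mean_maps(panel)
  expect_equal(maps$means$fusion, v_f)
  expect_equal(maps$means$wt, v_w)
  expect_equal(maps$difference, matrix(3, 5, 5))
  expect_equal(maps$sems$fusion, matrix(0, 5, 5))
})

test_that("class mean maps match brute-force per-cell averaging", {
  panel <- tiny_panel(n_frag = 5, n_per_class = 4, sd = 0.3, seed = 31)
  panel$matrices[[1]]$values[2, 4] <- panel$matrices[[1]]$values[4, 2] <- NA
  maps <- class_mean_maps(panel)
  y <- panel$meta$mll_status
  for (cl in c("fusion", "wt")) {
    for (i in 1:5) for (j in 1:5) {
      cells <- vapply(panel$matrices[y == cl],
                      function(m) m$values[i, j], 0)
      expect_equal(maps$means[[cl]][i, j], mean(cells, na.rm = TRUE))
    }
  }
  # cell missing in one fusion sample: mean over the rest, sem adapts
  expect_false(is.na(maps$means$fusion[2, 4]))
})

test_that("vectorized t-tests agree with stats::t.test in both variants", {
  panel <- tiny_panel(n_frag = 5, n_per_class = 6, sd = 0.25,
                      planted = cbind(2, 4), fold = 2, seed = 17)
  idx <- build_feature_index(panel)
  X <- feature_matrix(panel, idx)
  y <- panel$meta$mll_status
  for (ve in c(FALSE, TRUE)) {
    scores <- ttest_contacts(panel, alpha = 0.01, var_equal = ve)
    for (k in seq_len(nrow(idx))) {
      ref <- stats::t.test(X[y == "fusion", k], X[y == "wt", k],
                           var.equal = ve)
      expect_equal(scores$t_stat[k], unname(ref$statistic),
                   tolerance = 1e-10)
      expect_equal(scores$p_value[k], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate features follow the documented conventions", {
  mats <- lapply(1:6, function(k) contact_matrix(matrix(2, 4, 4)))
  names(mats) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = names(mats),
                     mll_status = rep(c("fusion", "wt"), each = 3),
                     subtype = "none", leukemia_type = "AML")
  panel <- sample_panel(mats, meta)
  scores <- ttest_contacts(panel)   # identical groups: t = 0, p = 1
  expect_true(all(scores$t_stat == 0))
  expect_true(all(scores$p_value == 1))
  expect_false(any(scores$passes))

  # constant within groups but different between: p -> 0, with a warning
  for (k in 1:3) mats[[k]]$values[] <- 5
  panel2 <- sample_panel(mats, meta)
  expect_warning(s2 <- ttest_contacts(panel2), "zero within-group")
  expect_true(all(s2$p_value == 0))
})

test_that("t statistic flips sign and p survives label swap", {
  panel <- tiny_panel(n_frag = 5, n_per_class = 5, sd = 0.2,
                      planted = cbind(1, 3), fold = 3, seed = 23)
  s1 <- ttest_contacts(panel)
  panel$meta$mll_status <- ifelse(panel$meta$mll_status == "fusion",
                                  "wt", "fusion")
  s2 <- ttest_contacts(panel)
  expect_equal(s1$t_stat, -s2$t_stat, tolerance = 1e-12)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
})

test_that("planted contacts are flagged informative and rank at the top", {
  planted <- cbind(c(1, 2, 3, 4), c(3, 5, 6, 6))
  panel <- tiny_panel(n_frag = 6, n_per_class = 15, sd = 0.2,
                      planted = planted, fold = 3, seed = 41)
  scores <- rank_informative_contacts(panel, alpha = 0.01)
  expect_equal(nrow(scores), 15)   # full upper triangle of 6 fragments
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  planted_keys <- key(planted[, 1], planted[, 2])
  top <- scores[seq_len(2 * nrow(planted)), ]
  expect_gte(sum(key(top$i, top$j) %in% planted_keys), 3)
  flagged <- scores[scores$informative, ]
  expect_gte(sum(key(flagged$i, flagged$j) %in% planted_keys), 3)
  # sorted by decreasing gain
  expect_true(!is.unsorted(rev(scores$info_gain_bits)))
})

test_that("panels without class signal yield (almost) no informative contacts", {
  panel <- tiny_panel(n_frag = 6, n_per_class = 10, sd = 0.25, seed = 53)
  scores <- rank_informative_contacts(panel, alpha = 0.01)
  expect_lte(sum(scores$informative), 2)   # type-I noise only
})

test_that("t-test type-I rate is calibrated at the null", {
  # null panels (no planted effects): fraction of features passing
  # P < 0.01 should be 0.01 up to Monte-Carlo error
  d <- sim_design(n_fragments = 20, noise_sigma = 0.3,
                  efficiency_sigma = 0, array_scale_range = c(1, 1),
                  class_sizes = c(`fusion:AF9` = 10, `wt:none` = 10))
  frac <- vapply(1:25, function(k) {
    sim <- simulate_panel(d, seed = 400 + k)
    mean(ttest_contacts(sim$panel, alpha = 0.01)$passes)
  }, 0)
  n_tests <- 25 * 20 * 19 / 2
  se <- sqrt(0.01 * 0.99 / n_tests)
  expect_lt(abs(mean(frac) - 0.01), 4 * se + 0.002)
})
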