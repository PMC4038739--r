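# Polynomial-kernel SVM trained by SMO: kernel algebra, closed-form duals,
# KKT feasibility, agreement with an independent solver, and the
# one-vs-one multiclass reduction.

kkt_feasible <- function(m, tol = 1e-6) {
  C <- m$config$cost
  all(m$alpha >= -tol, m$alpha <= C + tol) &&
    abs(sum(m$alpha * m$y)) < 1e-3 + tol
}

test_that("polynomial kernel matches its closed form", {
  expect_equal(poly_kernel(c(1, 1), c(1, 1), degree = 1), 2)
  expect_equal(poly_kernel(c(1, 2), c(3, 4), degree = 2), 121)  # (3+8)^2
  expect_equal(poly_kernel(c(1, 0), c(0, 1), degree = 3), 0)    # orthogonal
  expect_equal(poly_kernel(c(1, 2), c(3, 4), degree = 2, offset = 1), 144)
  # Gram form agrees with pairwise evaluation
  X <- matrix(rnorm(12), 4, 3)
  G <- poly_kernel(X, X, degree = 2)
  for (a in 1:4) for (b in 1:4) {
    expect_equal(G[a, b], poly_kernel(X[a, ], X[b, ], degree = 2))
  }
  expect_error(poly_kernel(1:2, 1:3), "mismatch")
})

test_that("two-point problem recovers the closed-form dual", {
  # x1 = 0 (+1), x2 = 2 (-1): boundary at 1, alpha = 2 / |x1 - x2|^2 = 0.5
  m <- svm_train(matrix(c(0, 2), ncol = 1), c(1, -1),
                 svm_config(degree = 1, cost = 1000))
  expect_equal(unname(m$alpha), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$bias, 1, tolerance = 1e-6)
  expect_equal(predict(m, matrix(1), type = "decision"), 0,
               tolerance = 1e-6)
  expect_equal(predict(m, matrix(0.5)), "1")
  expect_equal(predict(m, matrix(1.5)), "-1")
  expect_true(kkt_feasible(m))
  # a free support vector sits on the margin: |f| = 1
  expect_equal(abs(predict(m, matrix(0), type = "decision")), 1,
               tolerance = 1e-3)
})

test_that("XOR is solved by the quadratic kernel but not the linear one", {
  X <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  y <- c("in", "in", "out", "out")
  m2 <- svm_train(X, y, svm_config(degree = 2, cost = 100))
  expect_equal(predict(m2, X), y)
  m2i <- svm_train(X, y, svm_config(degree = 2, cost = 100, offset = 1))
  expect_equal(predict(m2i, X), y)
  m1 <- svm_train(X, y, svm_config(degree = 1, cost = 100))
  expect_gt(sum(predict(m1, X) != y), 0)
})

test_that("training order does not change the decision function", {
  blobs <- separable_blobs(n_per = 10, d = 4, seed = 2)
  cfg <- svm_config(kkt_tol = 1e-7)   # tight convergence isolates the dual
  m <- svm_train(blobs$X, blobs$y, cfg)
  perm <- sample(length(blobs$y))
  mp <- svm_train(blobs$X[perm, , drop = FALSE], blobs$y[perm], cfg)
  grid <- matrix(rnorm(40), ncol = 4)
  expect_equal(predict(m, grid, type = "decision"),
               predict(mp, grid, type = "decision"), tolerance = 1e-6)
})

test_that("trained duals are feasible and signs agree with an independent solver", {
  skip_if_not_installed("e1071")
  for (seed in 1:20) {
    set.seed(seed)
    n_per <- sample(5:20, 1)
    d <- sample(2:10, 1)
    blobs <- separable_blobs(n_per = n_per, d = d, gap = 5, seed = seed)
    m <- svm_train(blobs$X, blobs$y, svm_config(degree = 1, cost = 10))
    expect_true(kkt_feasible(m))
    # separable at this gap: training error should be zero
    expect_equal(predict(m, blobs$X), blobs$y)
    ref <- e1071::svm(blobs$X, factor(blobs$y), kernel = "linear",
                      cost = 10, scale = FALSE)
    ref_pred <- as.character(predict(ref, blobs$X))
    expect_equal(predict(m, blobs$X), ref_pred)
  }
})

test_that("degenerate label sets are rejected", {
  X <- matrix(rnorm(10), 5)
  expect_error(svm_train(X, rep("a", 5)), "degenerate")
})

test_that("one-vs-one multiclass reduces to the binary machine for k = 2", {
  blobs <- separable_blobs(n_per = 6, d = 3, seed = 3)
  mb <- svm_train(blobs$X, blobs$y,
                  class_labels = sort(unique(blobs$y)))
  mm <- svm_train_multiclass(blobs$X, blobs$y)
  expect_length(mm$models, 1)
  expect_equal(predict(mm, blobs$X), predict(mb, blobs$X))
})

test_that("three separated blobs are perfectly classified with 3 pairwise models", {
  set.seed(4)
  X <- rbind(matrix(rnorm(16), ncol = 2),
             matrix(rnorm(16, mean = 8), ncol = 2),
             cbind(rnorm(8, mean = 8), rnorm(8, mean = -8)))
  y <- rep(c("A", "B", "C"), each = 8)
  m <- svm_train_multiclass(X, y, svm_config(cost = 10))
  expect_length(m$models, 3)
  expect_equal(predict(m, X), y)
  votes <- predict(m, X, type = "votes")
  expect_equal(dim(votes), c(24L, 3L))
})

test_that("models serialize to JSON and restore identical predictions", {
  blobs <- separable_blobs(n_per = 6, d = 3, seed = 9)
  panel <- tiny_panel(n_frag = 6, n_per_class = 4, sd = 0.15,
                      planted = cbind(c(1, 2), c(4, 5)), seed = 5)
  fit <- dsp(panel, "mll_status")
  tf <- withr::local_tempfile(fileext = ".json")
  write_dsp(fit, tf)
  back <- read_dsp(tf)
  expect_equal(predict(back, panel), predict(fit, panel))
  expect_equal(predict(back, panel, type = "decision"),
               predict(fit, panel, type = "decision"), tolerance = 1e-12)
})
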