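test_that("well-separated one-dimensional classes are fit and classified perfectly", {
  set.seed(1)
  X <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)), ncol = 1)
  y <- rep(c("A", "B"), each = 20)
  m <- fit_lda(X, y)
  expect_equal(predict(m, X), y)
  # the decision boundary sits near the midpoint
  expect_equal(predict(m, matrix(c(4.5, 5.5), ncol = 1)), c("A", "B"))
})

test_that("duplicating every sample leaves the model parameters unchanged", {
  set.seed(2)
  X <- matrix(rnorm(60), ncol = 3)
  y <- rep(c("A", "B"), each = 10)
  m1 <- fit_lda(X, y)
  m2 <- fit_lda(rbind(X, X), c(y, y))
  expect_equal(m1$class_means, m2$class_means)
  expect_equal(m1$priors, m2$priors)
  # pooled covariance denominators (n - g) differ, so compare shapes only
  expect_equal(dim(m1$pooled_covariance), dim(m2$pooled_covariance))
  expect_equal(predict(m1, X), predict(m2, X))
})

test_that("exact score ties go to the earlier class label", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)   # symmetric classes around 0
  y <- c("A", "A", "B", "B")
  m <- fit_lda(X, y, ridge = 0)
  expect_equal(predict(m, matrix(0, ncol = 1)), "A")
})

test_that("predictions agree with an independently coded Bayes rule and with MASS", {
  set.seed(3)
  n <- 60
  X <- rbind(matrix(rnorm(n, 0), ncol = 2), matrix(rnorm(n, 1.5), ncol = 2),
             matrix(rnorm(n, 3), ncol = 2))
  y <- rep(c("A", "B", "C"), each = n / 2)
  Xt <- matrix(rnorm(100, 1.5), ncol = 2)
  m <- fit_lda(X, y, ridge = 0)
  expect_equal(predict(m, Xt), bayes_rule_predict(Xt, y, X))
  mass_fit <- MASS::lda(X, grouping = factor(y))
  expect_equal(predict(m, Xt),
               as.character(predict(mass_fit, Xt)$class))
})

test_that("predictions are invariant to affine feature transforms (ridge 0)", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  y <- rep(c("A", "B"), each = 20)
  Xt <- matrix(rnorm(30), ncol = 2)
  A <- matrix(c(2, 0.5, -1, 3), 2, 2); b <- c(5, -7)
  tf <- function(M) sweep(M %*% A, 2, b, "+")
  m0 <- fit_lda(X, y, ridge = 0)
  m1 <- fit_lda(tf(X), y, ridge = 0)
  expect_equal(predict(m0, Xt), predict(m1, tf(Xt)))
})

test_that("cross-validation is deterministic, bounded, and exact on separable data", {
  set.seed(5)
  X <- matrix(c(rnorm(30, 0, 0.05), rnorm(30, 5, 0.05)), ncol = 1)
  y <- rep(c("A", "B"), each = 30)
  cv <- cross_validate(X, y, k = 2, n_repeats = 10, seed = 7)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_identical(cv, cross_validate(X, y, k = 2, n_repeats = 10, seed = 7))
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  expect_error(cross_validate(X[1:31, , drop = FALSE], y[1:31], k = 30),
               ">= k")
})

test_that("the compiled CV kernel agrees exactly with the R fit/predict path", {
  set.seed(6)
  X <- matrix(rnorm(36 * 3), ncol = 3)
  y <- rep(c("A", "B", "C"), each = 12)
  classes <- sort(unique(y))
  k <- 2L; reps <- 5L; seed <- 11L
  cv <- cross_validate(X, y, k = k, n_repeats = reps, seed = seed)
  folds <- ratiomics:::with_seed(seed,
    ratiomics:::make_stratified_folds(y, classes, k, reps))
  manual <- vapply(seq_len(reps), function(r) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds[, r] != f
      m <- fit_lda(X[tr, , drop = FALSE], y[tr])
      mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, 0))
  }, 0)
  expect_equal(cv$fold_accuracies, manual, tolerance = 1e-12)
})

test_that("label-shuffled 3-class data cross-validates at chance", {
  # 100 independent label shuffles, one stratified 2-fold split each
  accs <- vapply(1:100, function(s) {
    w <- null_world(1300 + s, n_per_class = 10, d = 2)
    cross_validate(w$X, w$y, k = 2, n_repeats = 1, seed = s)$mean_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(fit_lda(X, c("A", rep("B", 9))), ">= 2 samples")
  expect_error(fit_lda(X, rep("A", 10)), ">= 2 classes")
  m <- fit_lda(matrix(rnorm(20), ncol = 2), rep(c("A", "B"), 5))
  expect_error(predict(m, matrix(1, ncol = 3)), "features")
  expect_warning(fit_lda(matrix(rnorm(8 * 10), ncol = 10),
                         rep(c("A", "B"), 4)), "ill-posed")
})
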