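test_that("full-rank PLS equals OLS and one-column PLS equals simple regression", {
  set.seed(31)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(x %*% c(1, -2, 0.5, 0)) + rnorm(50, sd = 0.3)
  m <- fit_pls(x, y, n_lv = 4)
  expect_equal(unname(coef(m)), unname(coef(lm(y ~ x))), tolerance = 1e-8)
  x1 <- x[, 1, drop = FALSE]
  m1 <- fit_pls(x1, y, n_lv = 1)
  expect_equal(unname(coef(m1)[2]), unname(coef(lm(y ~ x1))[2]), tolerance = 1e-10)
  expect_error(fit_pls(x, y, n_lv = 5), "rank")
})

test_that("PLS latent and collapsed-coefficient predictions coincide", {
  set.seed(32)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- x[, 1] - x[, 2] + rnorm(40, sd = 0.2)
  m <- fit_pls(x, y, n_lv = 3)
  # latent route: scores %*% q + y_mean must equal the coefficient route
  expect_equal(unname(m$fitted), unname(predict(m, x)), tolerance = 1e-10)
  # training R2 is non-decreasing in the number of latent variables
  r2 <- sapply(1:6, function(a) {
    f <- fit_pls(x, y, a)
    1 - sum((y - f$fitted)^2) / sum((y - mean(y))^2)
  })
  expect_true(all(diff(r2) >= -1e-12))
  # duplicated rows predict identically; missing columns error
  xx <- x[c(1, 1), ]
  expect_equal(predict(m, xx)[1], predict(m, xx)[2])
  expect_error(predict(m, x[, 1:3]), "missing column")
})

test_that("PLS agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(33)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(x %*% c(2, -1, 0, 1, 0.5)) + rnorm(60, sd = 0.4)
  xnew <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, colnames(x)))
  for (a in c(1, 3)) {
    mine <- predict(fit_pls(x, y, a), xnew)
    ref <- mixOmics::pls(x, y, ncomp = a, mode = "regression", scale = TRUE)
    theirs <- predict(ref, xnew)$predict[, , a]
    expect_equal(unname(mine), unname(theirs), tolerance = 1e-6)
  }
})

test_that("LDA separates synthetic Gaussian clouds and uses the midpoint threshold", {
  set.seed(34)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  colnames(x) <- c("a", "b")
  lab <- factor(rep(c("inactive", "active"), each = 30), levels = c("inactive", "active"))
  m <- fit_lda(x, lab)
  expect_equal(mean(predict(m, x) == lab), 1.0)
  expect_lt(m$wilks_lambda, 0.1)
  # identical class distributions: lambda near 1
  set.seed(35)
  x0 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  m0 <- fit_lda(x0, factor(rep(c("inactive", "active"), 50)))
  expect_gt(m0$wilks_lambda, 0.9)
  # one descriptor: threshold is the midpoint of projected class means
  x1 <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1, dimnames = list(NULL, "d"))
  lab1 <- factor(c("inactive", "inactive", "inactive", "active", "active", "active"),
                 levels = c("inactive", "active"))
  m1 <- fit_lda(x1, lab1)
  s <- predict(m1, x1, type = "score")
  expect_equal(unname(m1$threshold), mean(c(mean(s[1:3]), mean(s[4:6]))), tolerance = 1e-10)
  expect_error(fit_lda(x, factor(rep("a", 60))), "two classes")
})

test_that("bagged trees are deterministic given the seed and track LDA on separable data", {
  set.seed(36)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  colnames(x) <- c("a", "b")
  lab <- factor(rep(c("inactive", "active"), each = 50), levels = c("inactive", "active"))
  m1 <- fit_bagged_trees(x, lab, seed = 1)
  m2 <- fit_bagged_trees(x, lab, seed = 1)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_identical(m1$cv$predictions, m2$cv$predictions)
  lda_acc <- mean(predict(fit_lda(x, lab), x) == lab)
  expect_gte(m1$cv$accuracy, lda_acc - 0.05)
  expect_error(fit_bagged_trees(x, factor(rep("a", 100))), "two classes")
  # tiny class: folds reduced with a warning
  x_small <- x[c(1:3, 51:98), ]
  lab_small <- lab[c(1:3, 51:98)]
  expect_warning(fit_bagged_trees(x_small, lab_small, cv_folds = 10), "reducing folds")
})

test_that("stacking with four identical inputs spreads the single-copy slope evenly", {
  set.seed(37)
  y <- rnorm(50, 5, 1)
  p <- y + rnorm(50, sd = 0.3)
  inputs <- cbind(QSARpred = p, RASARpred = p, ARKApred = p, Hybridpred = p)
  m <- stack_models(inputs, y)
  co <- coef(m)[-1]
  expect_equal(unname(co), rep(co[[1]], 4), tolerance = 1e-10)   # symmetric
  slope1 <- unname(coef(lm(y ~ p))[2])
  expect_equal(sum(co), slope1, tolerance = 1e-8)                 # sums to the simple slope
  # four independent noisy copies: each coefficient ~ 1/4 of the single-copy slope
  inputs2 <- sapply(1:4, function(i) y + rnorm(50, sd = 0.3))
  colnames(inputs2) <- colnames(inputs)
  m2 <- stack_models(inputs2, y)
  co2 <- coef(m2)[-1]
  expect_equal(unname(co2), rep(mean(co2), 4), tolerance = 0.12)
  expect_error(stack_models(inputs[, 1:3], y), "four")
  inputs3 <- inputs; inputs3[, 2] <- 1
  expect_error(stack_models(inputs3, y), "constant")
})
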