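test_that("regression metrics reproduce hand-computed cases", {
  # perfect predictions
  y <- c(1, 2, 3, 4); p <- y
  r <- regression_metrics(y, p, p, c(2, 3), c(2, 3))
  expect_equal(r$R2, 1); expect_equal(r$Q2_F1, 1); expect_equal(r$Q2_F2, 1)
  expect_equal(r$CCC, 1); expect_equal(r$MAE_test, 0); expect_equal(r$RMSEp, 0)
  # test predictions at the train mean give Q2_F1 = 0
  tr <- c(4, 5, 6)                                  # mean 5
  r2 <- regression_metrics(tr, tr, tr, c(4, 6), c(5, 5))
  expect_equal(r2$Q2_F1, 0)
  expect_equal(r2$MAE_test, 1)
  expect_equal(r2$RMSEp, 1)
  # anti-correlated pair: CCC = -1
  expect_equal(rasarstack:::lin_ccc(c(0, 1), c(1, 0)), -1)
  expect_error(regression_metrics(rep(1, 5), rep(1, 5)), "constant")
})

test_that("Q2_F1 equals Q2_F2 exactly when the test mean matches the train mean", {
  set.seed(41)
  tr_obs <- rnorm(30, 5)
  te_obs <- c(rnorm(10, 5))
  te_obs <- te_obs - mean(te_obs) + mean(tr_obs)     # force equal means
  te_pred <- te_obs + rnorm(10, sd = 0.3)
  r <- regression_metrics(tr_obs, tr_obs, tr_obs, te_obs, te_pred)
  expect_equal(r$Q2_F1, r$Q2_F2, tolerance = 1e-12)
  # and differ when the means differ
  r2 <- regression_metrics(tr_obs, tr_obs, tr_obs, te_obs + 1, te_pred + 1)
  expect_false(isTRUE(all.equal(r2$Q2_F1, r2$Q2_F2)))
  expect_gt(r2$Q2_F1, r2$Q2_F2)   # shifted test mean inflates the F1 denominator
})

test_that("CCC never exceeds the Pearson correlation in absolute value", {
  set.seed(42)
  for (i in 1:50) {
    a <- rnorm(20); b <- rnorm(20) + 0.5 * a
    expect_lte(abs(rasarstack:::lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("LOO cross-validation refits without each compound", {
  set.seed(43)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(x %*% c(1, 2)) + 3                      # exactly linear
  loo <- loo_crossval(fit_mlr, x, y)
  expect_equal(loo, y, tolerance = 1e-8)            # Q2_LOO = 1
  r <- regression_metrics(y, y, loo)
  expect_equal(r$Q2_LOO, 1, tolerance = 1e-10)
  # pure-noise response: Q2_LOO below zero on average
  q2 <- replicate(60, {
    yn <- rnorm(30)
    loo_n <- loo_crossval(fit_mlr, x, yn)
    1 - sum((yn - loo_n)^2) / sum((yn - mean(yn))^2)
  })
  expect_lt(mean(q2), 0)
  # minimal n = 3 case runs
  expect_length(loo_crossval(fit_mlr, x[1:3, 1, drop = FALSE], y[1:3]), 3)
})

test_that("classification metrics match their definitions", {
  m <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(m[c("accuracy", "precision", "sensitivity", "specificity", "f1", "mcc")]),
               c(accuracy = 1, precision = 1, sensitivity = 1, specificity = 1, f1 = 1, mcc = 1))
  m2 <- classification_metrics(3, 4, 1, 2)
  expect_equal(m2$mcc, 10 / sqrt(600), tolerance = 1e-10)
  expect_equal(m2$accuracy, 0.7)
  # degenerate: everything predicted one class -> MCC 0, flagged
  m3 <- classification_metrics(0, 5, 0, 5)
  expect_equal(m3$mcc, 0)
  expect_true(m3$degenerate)
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("Y-randomization reports low intercepts for a real model and leaves X untouched", {
  d <- gen_regression_dataset(n = 80, p = 6, noise_sd = 0.55, seed = 44)
  x_before <- d$x + 0
  yr <- y_randomization(d$x, d$y, n_permutations = 50, seed = 9, model = "mlr")
  expect_identical(d$x, x_before)
  expect_lt(yr$R2Y_int, 0.3)
  expect_lt(yr$Q2Y_int, 0.05)
  expect_true(yr$pass)
  expect_equal(yr$table$correlation[1], 1)          # unpermuted point included
  expect_equal(nrow(yr$table), 51)
  # deterministic for a fixed seed
  yr2 <- y_randomization(d$x, d$y, n_permutations = 50, seed = 9, model = "mlr")
  expect_equal(yr$R2Y_int, yr2$R2Y_int)
  expect_error(y_randomization(d$x, rep(1, 80), 10, 1), "constant")
  expect_error(y_randomization(d$x, d$y, n_permutations = 5), ">= 10")
})

test_that("DModX normalizes training residuals and flags gross outliers", {
  d <- gen_regression_dataset(n = 60, p = 6, noise_sd = 0.3, seed = 45)
  m <- fit_pls(d$x, d$y, n_lv = 3)
  ad <- dmodx(m, d$x, is_training = TRUE)
  expect_equal(mean(ad$dmodx_norm^2), (60 - 3 - 1) / 60, tolerance = 1e-8)
  expect_gt(attr(ad, "crit"), 1)
  # a row reproduced exactly by the latent space has DModX 0:
  # project a training row onto the model plane and rebuild it
  X <- sweep(sweep(d$x, 2, m$x_mean), 2, m$x_sd, "/")
  TT <- X %*% m$weights %*% solve(t(m$loadings) %*% m$weights)
  X_hat <- TT %*% t(m$loadings)
  x_flat <- sweep(sweep(X_hat, 2, m$x_sd, "*"), 2, m$x_mean, "+")
  colnames(x_flat) <- colnames(d$x)
  ad0 <- dmodx(m, x_flat[1:5, ])
  expect_equal(ad0$dmodx_abs, rep(0, 5), tolerance = 1e-8)
  # 10-SD outlier in one descriptor is outside the 99% domain
  q <- d$x[1, , drop = FALSE]
  q[1, 1] <- q[1, 1] + 10 * sd(d$x[, 1])
  adq <- dmodx(m, q)
  expect_true(adq$outside)
})

test_that("prediction quality composes the three reliability rules", {
  d <- gen_regression_dataset(n = 60, p = 6, noise_sd = 0.3, seed = 46)
  m <- fit_pls(d$x, d$y, n_lv = 3)
  loo <- loo_crossval(function(x, y) fit_pls(x, y, 3), d$x, d$y)
  ram <- read_across(d$x, d$y, ra_hyperparams("GK", sigma = 2, n_close = 10))
  err <- abs(d$y - loo)
  # a training compound re-queried from a well-covered neighborhood:
  # inside AD, good neighborhood, in range
  pq_all <- prediction_quality(predict(m, d$x), !dmodx(m, d$x)$outside, ram, d$x, err)
  good_id <- which(pq_all$good_neighborhood)[1]
  q <- d$x[good_id, , drop = FALSE]
  ad <- dmodx(m, q)
  pq <- prediction_quality(predict(m, q), !ad$outside, ram, q, err)
  expect_equal(pq$category, "good")
  # gross AD outlier with an absurd prediction: bad
  q2 <- d$x[3, , drop = FALSE] + 12
  ad2 <- dmodx(m, q2)
  pq2 <- prediction_quality(1e3, !ad2$outside, ram, q2, err)
  expect_equal(pq2$category, "bad")
  # failing exactly one rule gives moderate: same good query, forced AD failure
  pq3 <- prediction_quality(predict(m, q), FALSE, ram, q, err)
  expect_equal(pq3$category, "moderate")
})
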