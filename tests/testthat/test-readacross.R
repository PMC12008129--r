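test_that("standardization uses training statistics only", {
  tr <- matrix(c(1, 3, 2, 6), 2, 2, dimnames = list(NULL, c("a", "b")))
  te <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("a", "b")))
  std <- standardize_blocks(tr, te)
  expect_equal(colMeans(std$train), c(a = 0, b = 0))
  expect_equal(apply(std$train, 2, sd), c(a = 1, b = 1))
  # hand-computed: a: mean 2 sd sqrt(2); b: mean 4 sd 2*sqrt(2)
  expect_equal(unname(std$apply[1, ]), c((1 - 2) / sqrt(2), (2 - 4) / (2 * sqrt(2))))
  # a test row equal to a train row maps to the same z-vector
  std2 <- standardize_blocks(tr, tr[2, , drop = FALSE])
  expect_equal(unname(std2$apply[1, ]), unname(std2$train[2, ]))
  expect_error(standardize_blocks(cbind(a = c(1, 1)), cbind(a = c(1, 1))), "zero training SD")
})

test_that("kernel similarities follow the conventional forms", {
  z <- c(1, 2, 3)
  for (k in c("ED", "GK", "LK")) {
    expect_equal(kernel_similarity(z, z, ra_hyperparams(k)), 1)
  }
  # d = 2 in one coordinate
  a <- c(0, 0); b <- c(2, 0)
  expect_equal(kernel_similarity(a, b, ra_hyperparams("GK", sigma = 2)), exp(-0.5), tolerance = 1e-10)
  expect_equal(kernel_similarity(a, b, ra_hyperparams("LK", gamma = 2)), exp(-1), tolerance = 1e-10)
  expect_equal(kernel_similarity(a, b, ra_hyperparams("ED")), 1 / 3)
  # strictly decreasing in distance
  d <- seq(0, 5, by = 0.25)
  for (k in c("ED", "GK", "LK")) {
    s <- sapply(d, function(dd) kernel_similarity(c(0, 0), c(dd, 0), ra_hyperparams(k)))
    expect_true(all(diff(s) < 0))
  }
  expect_error(ra_hyperparams("GK", sigma = -1))
  expect_error(ra_hyperparams("GK", n_close = 1))
})

test_that("close sources are the most similar, with documented tie-break and self-exclusion", {
  z <- matrix(c(0, 1, 2, 3, 10), ncol = 1, dimnames = list(paste0("s", 1:5), "x"))
  css <- close_sources(0.4, z, 1:5, params = ra_hyperparams("GK", sigma = 1, n_close = 3))
  expect_equal(css$source_ids, c("s1", "s2", "s3"))
  expect_true(all(diff(css$similarities) <= 0))
  # query identical to a source ranks it first with similarity 1
  css2 <- close_sources(2, z, 1:5, params = ra_hyperparams("LK", gamma = 1, n_close = 2))
  expect_equal(css2$source_ids[1], "s3")
  expect_equal(css2$similarities[1], 1)
  # tie: two equidistant sources -> lower id first
  zt <- matrix(c(-1, 1, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "x"))
  css3 <- close_sources(0, zt, 1:3, params = ra_hyperparams("GK", sigma = 1, n_close = 2))
  expect_equal(css3$source_ids, c("a", "b"))
  # self-exclusion via exclude
  css4 <- close_sources(0, z, 1:5, params = ra_hyperparams("GK", sigma = 1, n_close = 2),
                        exclude = "s1")
  expect_false("s1" %in% css4$source_ids)
  expect_error(close_sources(0, z[1, , drop = FALSE], 1,
                             params = ra_hyperparams("GK")), "fewer than 2")
})

test_that("read-across prediction is the similarity-weighted mean", {
  expect_equal(ra_predict(make_css(c(1, 1), c(4, 6))), 5.0)
  expect_equal(ra_predict(make_css(c(0.9, 0.1), c(4, 6))), 4.2, tolerance = 1e-12)
  expect_equal(ra_predict(make_css(c(0.3, 0.7, 0.2), rep(7, 3))), 7)
  expect_equal(ra_predict(make_css(c(0.9, 0.1), c(4, 6)), weighted = FALSE), 5.0)
})

test_that("predictions stay within the close-source response range", {
  d <- gen_regression_dataset(n = 60, seed = 13)
  m <- read_across(d$x, d$y, ra_hyperparams("GK", sigma = 2, n_close = 5))
  set.seed(99)
  q <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, colnames(d$x)))
  p <- predict(m, q)
  expect_true(all(p >= min(d$y) - 1e-12 & p <= max(d$y) + 1e-12))
  # leave-self-out: training predictions with self excluded never interpolate the own value only
  p_tr <- predict(m, d$x, self_exclude = TRUE)
  expect_true(all(is.finite(p_tr)))
})

test_that("hyperparameter optimization recovers the generating kernel and honors the grid", {
  # smooth response of descriptors: GK read-across should beat ED on sub-test RMSE
  set.seed(4)
  x <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(paste0("c", 1:80), paste0("x", 1:4)))
  y <- sin(x[, 1]) + x[, 2]^2 / 4 + 0.1 * rnorm(80)
  grid <- rbind(
    data.frame(kernel = "GK", sigma = c(1, 2), gamma = 1, n_close = 5),
    data.frame(kernel = "ED", sigma = 1, gamma = 1, n_close = 5))
  opt <- optimize_ra_hyperparams(x, y, grid, sub_split_seed = 2)
  expect_s3_class(opt$params, "ra_hyperparams")
  expect_equal(nrow(opt$report), nrow(grid))
  expect_equal(min(opt$report$rmse), opt$report$rmse[which(
    opt$report$kernel == opt$params$kernel &
    opt$report$n_close == opt$params$n_close &
    opt$report$sigma == opt$params$sigma)][1])
  # single-point grid returns that point
  single <- data.frame(kernel = "LK", sigma = 1, gamma = 0.5, n_close = 3)
  opt1 <- optimize_ra_hyperparams(x, y, single, sub_split_seed = 1)
  expect_equal(opt1$params$kernel, "LK")
  expect_equal(opt1$params$n_close, 3L)
  expect_error(optimize_ra_hyperparams(x, y, grid[0, ]), "empty grid")
  # the published salmon optimum (GK, n_close = 10, sigma = 2) is a legal default grid point
  g <- default_ra_grid()
  expect_true(any(g$kernel == "GK" & g$sigma == 2 & g$n_close == 10))
})
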