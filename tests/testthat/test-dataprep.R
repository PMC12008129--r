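test_that("pretreatment removes constant and inter-correlated columns", {
  set.seed(5)
  base <- rnorm(50)
  x <- cbind(a = base, b = base + rnorm(50, sd = 1e-3),  # r ~ 1
             c = rnorm(50), d = rep(2, 50))
  out <- pretreat(x)
  expect_false("d" %in% colnames(out$x))              # constant
  expect_equal(sum(c("a", "b") %in% colnames(out$x)), 1)  # one of the pair
  expect_true("c" %in% colnames(out$x))
  expect_true(all(c("d") %in% out$log$column))

  # 4-column matrix with one pair at r = 0.99 -> 3 columns remain
  set.seed(7)
  u <- rnorm(500)
  x2 <- cbind(p = u, q = 0.99 * u + sqrt(1 - 0.99^2) * rnorm(500),
              r = rnorm(500), s = rnorm(500))
  expect_gt(abs(cor(x2[, "p"], x2[, "q"])), 0.95)
  out2 <- pretreat(x2)
  expect_equal(ncol(out2$x), 3)
  expect_error(pretreat(matrix(1, 10, 2)), "all columns")
})

test_that("activity-based division gives the published 80/26 pattern and keeps extremes in training", {
  d <- gen_regression_dataset(n = 106, seed = 3)
  sp <- split_data(d$x, d$y, "activity", test_fraction = 26 / 106)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$test), 26)
  expect_setequal(c(sp$train, sp$test), rownames(d$x))
  extremes <- rownames(d$x)[c(which.min(d$y), which.max(d$y))]
  expect_true(all(extremes %in% sp$train))

  # n = 4: exactly one test compound, never the extreme responder
  x4 <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  y4 <- c(1, 5, 2, 9)
  sp4 <- split_data(x4, y4, "activity", test_fraction = 0.25)
  expect_equal(length(sp4$test), 1)
  expect_false(sp4$test %in% c("a", "d"))
})

test_that("Kennard-Stone picks the two endpoints of a line first", {
  x <- matrix(c(0, 1, 2, 3, 10), ncol = 1,
              dimnames = list(paste0("p", 1:5), "x"))
  sel <- rasarstack:::kennard_stone_select(scale(x), 2)
  expect_setequal(sel, c(1, 5))
  # full split keeps the most distant points in training
  sp <- split_data(x, 1:5, "kennard_stone", test_fraction = 0.4)
  expect_true(all(c("p1", "p5") %in% sp$train))
})

test_that("all four division methods partition the ids", {
  d <- gen_regression_dataset(n = 40, seed = 9)
  for (m in c("activity", "kennard_stone", "euclidean", "kmedoid")) {
    sp <- split_data(d$x, d$y, m, test_fraction = 0.25, seed = 4)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), rownames(d$x))
    expect_equal(length(sp$test), 10)
  }
  expect_error(split_data(d$x, d$y, "activity", test_fraction = 0.001), "incompatible")
})

test_that("best-subset selection recovers the generating descriptors", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * x[, 1] - x[, 3] + rnorm(60, sd = 0.05)
  bss <- best_subset_selection(x, y, subset_size = 2)
  expect_equal(nrow(bss), choose(5, 2))
  expect_setequal(strsplit(bss$combination[1], ",")[[1]], c("x1", "x3"))
  expect_true(all(diff(bss$q2_loo) <= 1e-12))   # sorted best-first

  # subset_size = p: the single combination equals the full-model LOO Q2
  bss_all <- best_subset_selection(x, y, subset_size = 5)
  expect_equal(nrow(bss_all), 1)
  full <- rasarstack:::ols_loo(x, y)
  expect_equal(bss_all$q2_loo, full$q2_loo, tolerance = 1e-12)

  # perfectly collinear pair degrades gracefully and ranks last
  x2 <- cbind(x[, 1:2], dup1 = x[, 1], dup2 = x[, 1])
  bss2 <- best_subset_selection(x2, y, subset_size = 2)
  expect_equal(bss2$q2_loo[nrow(bss2)], -Inf)
  expect_error(best_subset_selection(x, y, 2, cap = 3), "cap")
})

test_that("genetic selection matches exhaustive search on a small pool", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * x[, 1] - x[, 3] + rnorm(60, sd = 0.05)
  ga <- genetic_selection(x, y, "q2_loo", n_descriptors = 2,
                          ga_params = list(population = 30, generations = 15), seed = 2)
  expect_setequal(ga$best, c("x1", "x3"))
  expect_true(all(diff(ga$trace) >= 0))          # elitism: never decreases
  bss <- best_subset_selection(x, y, 2)
  expect_lte(ga$fitness, bss$q2_loo[1] + 1e-12)  # GA is a heuristic lower bound

  # degenerate GA: population 1, no generations -> seed-determined chromosome
  g0 <- genetic_selection(x, y, "q2_loo", 2, ga_params = list(population = 1, generations = 0), seed = 5)
  g0b <- genetic_selection(x, y, "q2_loo", 2, ga_params = list(population = 1, generations = 0), seed = 5)
  expect_identical(g0$best, g0b$best)
})

test_that("classification fitness reaches 1 on a perfectly separable pair", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  colnames(x) <- c("s1", "s2")
  x <- cbind(x, noise = rnorm(40))
  lab <- rep(c("inactive", "active"), each = 20)
  ga <- genetic_selection(x, lab, "mcc", n_descriptors = 2,
                          ga_params = list(population = 20, generations = 5), seed = 1)
  expect_equal(ga$fitness, 1.0)
})
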