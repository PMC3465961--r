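test_that("spearman matches perfect and reversed orderings", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_identical(spearman(x, x)$estimate, 1)
  expect_identical(spearman(x, -x)$estimate, -1)
  expect_error(spearman(x, rep(1, 6)), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("spearman and kendall match brute-force oracles on tied data", {
  withr::local_seed(77)
  for (i in 1:100) {
    n <- sample(5:10, 1)
    x <- sample(1:5, n, replace = TRUE) + stats::runif(n, 0, 0.01) *
      (stats::rbinom(n, 1, 0.5))
    y <- sample(1:4, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman(x, y)$estimate, oracle_spearman(x, y))
    expect_equal(kendall_tau(x, y)$estimate, oracle_kendall_taub(x, y))
  }
})

test_that("a single adjacent swap gives tau = 1 - 4/(n(n-1))", {
  for (n in c(5, 8, 12)) {
    y <- seq_len(n)
    y[c(2, 3)] <- y[c(3, 2)]
    expect_equal(kendall_tau(seq_len(n), y)$estimate, 1 - 4 / (n * (n - 1)))
  }
})

test_that("spearman and kendall agree in sign under strict monotone association", {
  withr::local_seed(13)
  for (i in 1:25) {
    x <- sample(100, 8)
    y <- if (i %% 2) exp(x / 50) else -x^3
    s <- spearman(x, y)$estimate
    k <- kendall_tau(x, y)$estimate
    expect_identical(sign(s), sign(k))
  }
})

test_that("pearson_r2 matches closed forms and a redundant computation path", {
  x <- c(1, 2, 3, 4, 5.5)
  expect_equal(pearson_r2(x, 2 * x + 1), list(r = 1, r_squared = 1))
  expect_equal(pearson_r2(x, -x)$r, -1)
  withr::local_seed(3)
  for (i in 1:100) {
    a <- stats::rnorm(10)
    b <- stats::rnorm(10) + a / 2
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r2(a, b)$r, manual)
  }
})

test_that("a degenerate pool collapses the null to a point with p = 1", {
  pool <- ortholog_pool(paste0("p", 1:20), rep(0.07, 20))
  rz <- randomization_null(pool, set_size = 5, n_reps = 200, seed = 1,
                           observed_mean = 0.07)
  expect_true(all(rz$null_means == 0.07))
  expect_identical(rz$empirical_p, 1)
})

test_that("the unconstrained null mean recovers the pool mean", {
  pool <- simulate_ortholog_pool(2000, seed = 8)
  rz <- randomization_null(pool, set_size = 16, n_reps = 5000, seed = 2)
  mc_se <- stats::sd(pool$omega) / sqrt(16) / sqrt(5000)
  expect_lt(abs(rz$null_mean_of_means - mean(pool$omega)), 3 * mc_se)
})

test_that("a composition constraint pulls the null toward the tagged-subset mean", {
  # tagged (Galpha-like) entries are more constrained: lower omega
  om_tag <- rep(0.05, 300)
  om_bg <- rep(0.2, 700)
  pool <- ortholog_pool(paste0("p", 1:1000), c(om_tag, om_bg),
                        tags = c(rep("Galpha", 300), rep("", 700)))
  un <- randomization_null(pool, 16, 2000, seed = 3)
  con <- randomization_null(pool, 16, 2000, seed = 3,
                            constraint = list(tag_label = "Galpha",
                                              required_count = 6))
  expect_lt(con$null_mean_of_means, un$null_mean_of_means)
  expect_gt(con$null_mean_of_means, mean(om_tag))
})

test_that("randomization is bit-reproducible, add-one p is never 0, errors are raised", {
  pool <- simulate_ortholog_pool(100, seed = 4)
  a <- randomization_null(pool, 8, 500, seed = 9, observed_mean = 0)
  b <- randomization_null(pool, 8, 500, seed = 9, observed_mean = 0)
  expect_identical(a$null_means, b$null_means)
  expect_identical(a$empirical_p, 1 / 501)  # observed below every null mean
  expect_error(randomization_null(pool, 8, 500,
                                  constraint = list(tag_label = "Galpha",
                                                    required_count = 2)),
               "unsatisfiable")
  expect_error(randomization_null(pool, 0, 10), "set_size")
})

test_that("without-replacement sets draw distinct pool entries", {
  pool <- ortholog_pool(paste0("p", 1:10), 1:10 / 10)
  rz <- randomization_null(pool, 10, 50, seed = 5,
                           replace_within_set = FALSE)
  expect_true(all(rz$null_means == mean(pool$omega)))
  expect_error(randomization_null(pool, 11, 10, seed = 1,
                                  replace_within_set = FALSE),
               "exceeds pool size")
})

test_that("histogram bins conserve counts and match direct counting", {
  expect_identical(histogram_bins(0.5, 0.1)$count, 1L)
  withr::local_seed(6)
  x <- stats::rnorm(500)
  h <- histogram_bins(x, 0.25)
  expect_identical(sum(h$count), 500L)
  for (k in seq_len(nrow(h)))
    expect_identical(h$count[k], sum(x >= h$lo[k] & x < h$hi[k]))
  expect_error(histogram_bins(x, 0), "positive")
  expect_error(histogram_bins(numeric(0), 1), "no values")
})
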