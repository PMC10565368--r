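toy_scores <- function(n = 24, seed = 1) {
  set.seed(seed)
  data.frame(site = sprintf("S%02d", 1:n),
             PC1 = sort(rnorm(n)), PC2 = rnorm(n))
}

test_that("the AICc correction term matches its closed form", {
  sc <- toy_scores()
  set.seed(2)
  y <- 1 + 0.5 * sc$PC1 + rnorm(24, 0, 0.3)
  reg <- fit_ols_aicc(y, sc)
  tab <- reg$table
  # k = 3 (intercept, slope, sigma^2) at n = 24: correction 2*3*4/20 = 1.2
  fit_pc1 <- lm(y ~ PC1, data = sc)
  expect_equal(tab$AICc[tab$candidate == "PC1"], AIC(fit_pc1) + 1.2,
               tolerance = 1e-12)
  expect_equal(tab$k[tab$candidate == "PC1"], 3)
  # the correction shrinks monotonically as n grows
  corr <- function(n, k = 3) 2 * k * (k + 1) / (n - k - 1)
  ns <- seq(10, 200, by = 10)
  expect_true(all(diff(corr(ns)) < 0))
  expect_lt(corr(1e6), 1e-4)
})

test_that("a noiseless PC1 signal selects the PC1 model with R^2 = 1", {
  sc <- toy_scores(seed = 3)
  y <- 2 - 1.5 * sc$PC1
  reg <- suppressWarnings(fit_ols_aicc(y, sc))
  expect_equal(reg$selected, "PC1")
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
})

test_that("pure-noise responses mostly select the intercept-only model", {
  sc <- toy_scores(seed = 4)
  set.seed(100)
  picks <- vapply(1:200, function(i) {
    fit_ols_aicc(rnorm(24), sc)$selected
  }, character(1))
  expect_gt(mean(picks == "1"), 0.5)
})

test_that("Moran's I matches a brute-force double loop on a toy layout", {
  coords <- cbind(x = c(0, 0, 0, 0, 0), y = c(1, 2, 3, 4, 5))
  x <- c(0.2, -1, 0.5, 2, -0.7)
  W <- spatial_weights(coords, row_standardize = FALSE)
  n <- 5
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  i_bf <- (n / sum(W)) * num / sum(z^2)
  expect_equal(morans_i(x, W = W), i_bf, tolerance = 1e-12)
  # a perfect spatial gradient has positive autocorrelation
  expect_gt(morans_i(coords[, "y"], coords), 0)
  expect_error(morans_i(rep(1, 5), coords), "zero-variance")
})

test_that("Moran's I agrees with ape's implementation", {
  skip_if_not_installed("ape")
  set.seed(8)
  coords <- cbind(runif(10), runif(10))
  x <- rnorm(10)
  W <- spatial_weights(coords, row_standardize = TRUE)
  expect_equal(morans_i(x, W = W),
               ape::Moran.I(x, W)$observed, tolerance = 1e-10)
})

test_that("Moran's I shifts with a constant and duplicate sites get a floor", {
  set.seed(12)
  coords <- cbind(runif(8), runif(8))
  x <- rnorm(8)
  W <- spatial_weights(coords)
  expect_equal(morans_i(x, W = W), morans_i(x + 100, W = W),
               tolerance = 1e-12)
  dup <- rbind(coords, coords[1, ])
  expect_warning(spatial_weights(dup), "minimum-distance floor")
})

test_that("the permutation test is deterministic and detects gradients", {
  set.seed(30)
  n <- 24
  coords <- cbind(x = runif(n, 0, 1000), y = seq(0, 100000, length.out = n))
  res <- morans_i_permutation(coords[, "y"] + rnorm(n, 0, 1000), coords,
                              n_perm = 999, seed = 5)
  expect_lte(res$p_value, 0.05)
  res2 <- morans_i_permutation(coords[, "y"] + rnorm(n, 0, 1000), coords,
                               n_perm = 999, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  expect_error(morans_i_permutation(rnorm(n), coords, n_perm = 50),
               "configuration error")
  # permutation distribution is centred on -1/(n-1)
  expect_equal(res$expected, -1 / (n - 1))
  se <- sd(res$perm_I) / sqrt(length(res$perm_I))
  expect_lt(abs(mean(res$perm_I) - res$expected), 4 * se + 0.01)
})

test_that("Wilcoxon p-values match full sign enumeration", {
  # all-positive differences at n = 6: exact two-sided p = 2/2^6
  res6 <- paired_tests(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
  expect_equal(res6$p_value, 0.03125, tolerance = 1e-12)
  expect_true(res6$exact)

  set.seed(55)
  for (n in 5:10) {
    x_b <- rnorm(n)
    x_a <- x_b + rnorm(n, 0.3)
    res <- paired_tests(x_a, x_b)
    expect_equal(res$p_value, wilcox_enum_p(x_a - x_b), tolerance = 1e-12)
  }
})

test_that("the Wilcoxon statistic is rank-invariant to scaling", {
  set.seed(66)
  x_b <- rnorm(8)
  x_a <- x_b + rnorm(8)
  r1 <- paired_tests(x_a, x_b)
  r2 <- paired_tests(x_b + 2 * (x_a - x_b), x_b)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("mirrored differences give no evidence of a shift", {
  d <- c(-3, -2, -1, 1, 2, 3)
  res <- paired_tests(d, rep(0, 6))
  expect_gt(res$p_value, 0.9)
})

test_that("the normality flag follows the Shapiro-Wilk test", {
  set.seed(77)
  normal_d <- rnorm(20)
  res_n <- paired_tests(normal_d, rep(0, 20))
  expect_equal(res_n$shapiro_p, shapiro.test(normal_d)$p.value)
  skewed <- c(rexp(19, 0.2), -0.1)
  res_s <- paired_tests(skewed, rep(0, 20))
  expect_false(res_s$normal)
  expect_error(paired_tests(c(1, 1, 0), c(1, 1, 0)), "equal length|degenerate")
})
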