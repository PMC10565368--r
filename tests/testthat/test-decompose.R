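test_that("the model recovers signals in its own span exactly", {
  t <- 1:52
  d <- fit_tslm(sin(2 * pi * t / 26), m = 26)
  expect_equal(unname(d$coefficients),
               c(0, 0, 1, 0), tolerance = 1e-8)
  expect_lt(max(abs(d$remainder)), 1e-8)

  d_const <- fit_tslm(rep(3.7, 52), m = 26)
  expect_equal(unname(d_const$coefficients), c(3.7, 0, 0, 0),
               tolerance = 1e-8)

  d_trend <- fit_tslm(0.1 * t, m = 26)
  expect_equal(unname(d_trend$coefficients["b1"]), 0.1, tolerance = 1e-8)
  expect_lt(max(abs(d_trend$seasonal)), 1e-8)

  # arbitrary coefficients in the span
  set.seed(14)
  for (i in 1:5) {
    b <- rnorm(4)
    y <- b[1] + b[2] * t + b[3] * sin(2 * pi * t / 26) +
      b[4] * cos(2 * pi * t / 26)
    expect_equal(unname(fit_tslm(y, 26)$coefficients), b,
                 tolerance = 1e-8)
  }
})

test_that("components add back to the observed series", {
  set.seed(2)
  y <- rpois(52, 20) + 5 * sin(2 * pi * (1:52) / 26)
  d <- fit_tslm(y, 26)
  expect_lt(max(abs(d$trend + d$seasonal + d$remainder - y)), 1e-8)
  expect_lt(abs(mean(d$remainder)), 1e-8)
  # seasonal component has period m
  expect_equal(d$seasonal[1:26], d$seasonal[27:52], tolerance = 1e-8)
})

test_that("missing periods are excluded from the fit but still evaluated", {
  t <- 1:52
  y <- 2 + 0.05 * t + sin(2 * pi * t / 26)
  y_na <- y
  y_na[c(5, 17, 40)] <- NA
  d <- fit_tslm(y_na, 26)
  expect_equal(unname(d$coefficients), c(2, 0.05, 1, 0), tolerance = 1e-8)
  expect_false(anyNA(d$seasonal))
  expect_true(all(is.na(d$remainder[c(5, 17, 40)])))
  expect_error(fit_tslm(y[1:20], 26), "annual cycle")
})

test_that("component variances of a pure sinusoid are A^2/2", {
  t <- 1:52
  A <- 3
  d <- fit_tslm(A * sin(2 * pi * t / 26 + 0.7), 26)
  v <- component_variances(d)
  # population variance of a sinusoid over full cycles is exactly A^2/2
  expect_equal(unname(v$absolute["seasonal"]), A^2 / 2, tolerance = 1e-6)
  expect_equal(unname(v$relative["seasonal"]), 1, tolerance = 1e-6)
  expect_equal(sum(v$relative), 1, tolerance = 1e-10)

  d0 <- fit_tslm(rep(1, 52), 26)
  v0 <- component_variances(d0)
  expect_true(v0$degenerate)
  expect_true(all(is.na(v0$relative)))
})

test_that("equal seasonal and noise power split the relative variance", {
  # y = A sin + noise with sigma^2 = A^2/2: relative seasonality ~ 0.5
  set.seed(77)
  t <- 1:52
  A <- 2
  sigma <- sqrt(A^2 / 2)
  rels <- vapply(1:300, function(i) {
    y <- A * sin(2 * pi * t / 26) + rnorm(52, 0, sigma)
    component_variances(fit_tslm(y, 26))$relative["seasonal"]
  }, numeric(1))
  se <- sd(rels) / sqrt(length(rels))
  expect_lt(abs(mean(rels) - 0.5), 3 * se + 0.02)
})

test_that("synchrony hits its analytic anchors", {
  x <- rpois(52, 10) + sin(1:52)
  expect_equal(loreau_synchrony(rbind(x, x))$phi, 1, tolerance = 1e-12)
  expect_equal(loreau_synchrony(rbind(x, 50 - x))$phi, 0, tolerance = 1e-12)
  flat <- loreau_synchrony(rbind(rep(1, 10), rep(2, 10)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$phi))
})

test_that("independent equal-variance series have synchrony near 1/2", {
  set.seed(42)
  phis <- vapply(1:400, function(i)
    loreau_synchrony(rbind(rnorm(100), rnorm(100)))$phi, numeric(1))
  expect_true(all(phis >= 0 & phis <= 1))
  se <- sd(phis) / sqrt(length(phis))
  expect_lt(abs(mean(phis) - 0.5), 3 * se + 0.01)
})

test_that("standardized seasonal curves are scale invariant", {
  t <- 1:52
  y <- 20 + 6 * sin(2 * pi * t / 26) + rnorm(52, 0, 1)
  d1 <- fit_tslm(y, 26)
  d2 <- fit_tslm(3 * y, 26)
  s1 <- standardize_seasonal(d1, sum(y))
  s2 <- standardize_seasonal(d2, sum(3 * y))
  expect_equal(s1, s2, tolerance = 1e-8)
  expect_equal(standardize_seasonal(d1, 10) * 0 + 0,
               rep(0, 52) * standardize_seasonal(d1, 10))
  expect_error(standardize_seasonal(d1, 0), "positive")
  # the group mean of identical standardized curves is either curve
  expect_equal(colMeans(rbind(s1, s1)), s1)
})

test_that("fitted amplitude recovers the generator's site-scale amplitude", {
  # a seasonal log-link signal fitted on the count scale still yields a
  # positive, amplitude-ordered seasonal variance
  cfg <- sim_config(n_sites = 6, n_stations = 1, n_periods = 52,
                    n_species = 1, seed = 21, dispersion = Inf,
                    trend_sd = 0, seasonal_gain = 3,
                    baseline_log_mean = log(50), baseline_log_sd = 0,
                    amplitude_log_sd = 0)
  meta <- generate_landscape(cfg)
  pool <- generate_species_pool(cfg, meta)
  tab <- simulate_counts(meta, pool, cfg)
  agg <- aggregate_activity(tab)
  mats <- series_matrices(agg)
  amp_fit <- vapply(meta$site, function(s) {
    d <- fit_tslm(as.vector(mats[[s]]), 26)
    sqrt(d$coefficients["gs"]^2 + d$coefficients["gc"]^2)
  }, numeric(1))
  amp_true <- pool$truth$amplitude[match(meta$site, pool$truth$site)]
  expect_gt(cor(amp_fit, amp_true, method = "spearman"), 0.9)
})
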