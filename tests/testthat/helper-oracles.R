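# Independent oracles used by both unit and acceptance tests.

# Brute-force Hellinger temporal beta diversity: explicit loops, no shared
# code with the implementation.
bd_bruteforce <- function(M) {
  Tn <- ncol(M)
  S <- nrow(M)
  H <- matrix(0, Tn, S)
  for (t in seq_len(Tn)) {
    tot <- 0
    for (j in seq_len(S)) tot <- tot + M[j, t]
    for (j in seq_len(S)) H[t, j] <- sqrt(M[j, t] / tot)
  }
  ss_j <- numeric(S)
  for (j in seq_len(S)) {
    mbar <- mean(H[, j])
    for (t in seq_len(Tn)) ss_j[j] <- ss_j[j] + (H[t, j] - mbar)^2
  }
  list(BD_total = sum(ss_j) / (Tn - 1), SCBD = ss_j / sum(ss_j))
}

# Enumeration oracle for the exact two-sided Wilcoxon signed-rank p-value:
# all 2^n equally likely sign assignments of the ranked |differences|.
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p1 <- if (w_obs > mu) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(2 * p1, 1)
}

# One seeded end-to-end run of the seasonality-recovery experiment:
# simulate the full monitoring design, condition the counts, rarefy, fit the
# decomposition per site, and regress the relative component variances on
# land-cover PC1.
rel_variance_recovery <- function(seed, gain, n_rep = 5) {
  cfg <- sim_config(n_sites = 24, n_stations = 3, n_periods = 52,
                    n_species = 40, seed = seed, seasonal_gain = gain)
  sim <- simulate_dataset(cfg)
  scores <- landcover_scores(sim$meta)
  agg <- aggregate_activity(apply_threshold(sim$counts, 500))
  mats <- series_matrices(agg)
  target <- min(vapply(mats, sum, numeric(1)))
  set.seed(seed + 10000L)
  rel <- t(vapply(mats, function(M) {
    reps <- rarefy_matrix(M, target, n_rep = n_rep)
    rr <- vapply(reps, function(R)
      component_variances(fit_tslm(colSums(R), 26))$relative[
        c("seasonal", "remainder")], numeric(2))
    rowMeans(rr)
  }, numeric(2)))
  pc1 <- scores$scores$PC1[match(rownames(rel), scores$scores$site)]
  cs <- summary(lm(rel[, 1] ~ pc1))$coefficients
  cr <- summary(lm(rel[, 2] ~ pc1))$coefficients
  c(slope_seas = cs[2, 1], p_seas = cs[2, 4],
    slope_rem = cr[2, 1], p_rem = cr[2, 4])
}
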