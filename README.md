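# seasonvar

Quantify and decompose the temporal variability of community activity time
series across an anthropogenic land-cover gradient.

Insect monitoring networks that sample passive traps at a fine cadence
(e.g. biweekly) produce, for every site, a species × time matrix of
*activity* counts. `seasonvar` asks what kind of temporal variability those
communities have — cyclic, directional, or stochastic — and how that
structure changes from forested to developed landscapes. It is aimed at
community ecologists analysing multi-site, multi-species count series, and
at anyone who wants a fully seeded, ground-truth-tested implementation of
the metric chain below.

## What it computes

For each site, after truncating extreme station-level counts and summing
stations to site level, and on activity rarefied to equal totals across
sites (multivariate hypergeometric subsampling of species × period cells):

- **Functional variability** — the coefficient of variation of the
  community-total series, CV = sd/mean.
- **Compositional variability** — temporal beta diversity: the total
  variance of the Hellinger-transformed species × time matrix,
  BD_total = SS_total/(T−1), with per-species contributions
  SCBD_j = SS_j/SS_total (summing to 1, also summed by alien status).
- **Time-series decomposition** — OLS fit of
  y(t) = β₀ + β₁t + γ_s sin(2πt/m) + γ_c cos(2πt/m), i.e. linear trend +
  annual Fourier term of order K = 1 (m = 26 biweekly periods per year),
  giving additive seasonal / trend / remainder components and their
  absolute and relative variances.
- **Richness** — observed, rarefied, and Hill-number (q = 0) extrapolated
  (Chao1 undetected-species correction, doubled sample size).
- **Synchrony** — Loreau–De Mazancourt
  φ = var(Σᵢ xᵢ(t)) / (Σᵢ sd xᵢ(t))² ∈ [0, 1].

Site-level responses are regressed on land-cover PCA scores (arcsine-sqrt
transformed class proportions; PC1 = forested↔developed) with AICc model
selection over {1, PC1, PC2, PC1+PC2} and Moran's I permutation tests on
the selected model's residuals. A between-group comparison rarefies each
shared species to its minimum total between the forested and developed
site groups, fits the decomposition per group, and tests the paired
relative seasonality variances with a Wilcoxon signed-rank test.

A seeded synthetic-data generator (`sim_config()`, `simulate_dataset()`)
emulates the whole monitoring design — 24 sites × 3 stations × 52 biweekly
periods, negative-binomial counts with log-link seasonality whose
amplitude covaries with forest cover — so the entire chain has
ground-truth recovery tests.

## Worked example

```r
library(seasonvar)

cfg <- sim_config(n_sites = 24, n_species = 40, seed = 42)
sim <- simulate_dataset(cfg)
res <- run_full_analysis(sim$counts, sim$meta, sim$species,
                         n_rep = 20, n_perm = 999, seed = 42)
print(res)
```

```
seasonvar full analysis: 24 sites,  rarefaction target 7306
Selected models (response: predictors, R^2):
  log_total_activity     PC1+PC2  R^2 = 0.930
  cv                     PC1      R^2 = 0.945
  bd_total               PC1      R^2 = 0.915
  var_seasonal           PC1      R^2 = 0.927
  var_trend              1        R^2 = 0.000
  var_remainder          PC1      R^2 = 0.503
  rel_seasonal           PC1      R^2 = 0.564
  rel_trend              1        R^2 = 0.000
  rel_remainder          PC1      R^2 = 0.550
  scbd_native            PC1      R^2 = 0.165
  scbd_alien             1        R^2 = 0.000
  scbd_uncertain         PC1      R^2 = 0.275
```

Sites vary 24-fold in total activity, so all variability metrics are
computed at the common rarefaction target (here 7306 individuals). With
the generator's default seasonal gain, functional variability (CV),
compositional variability (BD) and the seasonal component variance all
increase strongly towards the forested end of PC1, while the *relative*
remainder (stochastic) share moves the opposite way — seasonality is
traded against stochasticity along the gradient. Trend variance is
selected as intercept-only: the generator drifts species only weakly.

```r
print(res$group_comparison)
```

```
Between-group seasonality comparison: 40 retained species

    alien    native uncertain
        7        23        10
Wilcoxon signed-rank: V = 818.0, p = 4.318e-08
```

The same species, rarefied to equal totals in the two groups, are more
seasonal (higher relative seasonality variance) in the forested group —
the paired difference is significant, so the contrast is within-species,
not a composition artefact.

```r
print(res$moran$rel_seasonal)
```

```
Moran's I = 0.0838 (E[I] = -0.0435), permutation p = 0.0170 (999 perms)
```

The permutation diagnostic flags residual spatial structure for this
response in this simulated landscape (the synthetic forest gradient runs
south–north), illustrating the check.

All tables can be written to CSV, with a run manifest, via
`write_results(res, "out/")`. A thin command-line wrapper with `simulate`,
`landcover` and `run-all` subcommands (including a `--threshold`
sensitivity sweep) is installed at
`system.file("scripts", "seasonvar-cli.R", package = "seasonvar")`.

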