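#' Simulation configuration for the synthetic monitoring design
#'
#' Builds and validates the configuration object consumed by
#' [generate_landscape()], [generate_species_pool()] and [simulate_counts()].
#' The defaults emulate a biweekly trap-count monitoring network: 24 sites,
#' each with 3 trap stations, sampled over 52 biweekly periods (2 years at 26
#' periods per year), with a species pool whose seasonal amplitude can be made
#' to covary with the forest cover surrounding each site.
#'
#' @param n_sites Number of monitoring sites.
#' @param n_stations Number of trap stations per site. Station-level counts
#'   are multinomial splits of the site-level activity, so summing stations
#'   back to the site level is lossless.
#' @param n_periods Total number of sampling periods; must be a multiple of
#'   `periods_per_year`.
#' @param periods_per_year Sampling periods per annual cycle (26 = biweekly).
#' @param n_species Size of the species pool.
#' @param seed Integer seed governing all randomness downstream.
#' @param seasonal_gain Dimensionless coefficient linking a site's forest
#'   proportion to the per-species log seasonal amplitude. With
#'   `seasonal_gain = 0` amplitudes are independent of land cover (the null
#'   scenario); positive values make communities in forested sites more
#'   seasonal.
#' @param trend_sd Standard deviation of the per-period linear drift in the
#'   log mean (directional trend component).
#' @param dispersion Negative-binomial size parameter for site-level counts.
#'   `Inf` gives Poisson counts (no overdispersion).
#' @param status_probs Named numeric vector of probabilities over the species
#'   status classes `native`, `alien`, `uncertain`; must sum to 1.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-species
#'   baseline log activity rate.
#' @param amplitude_log_mean,amplitude_log_sd Mean and SD of the per-species
#'   log seasonal amplitude at average forest cover.
#' @param habitat_match Coefficient coupling a species' habitat affinity to
#'   its baseline log rate (0 disables compositional turnover along the
#'   gradient).
#' @param phase_kappa Von Mises concentration of seasonal peak phases for
#'   forest-affiliated species; developed-affiliated species draw phases
#'   uniformly on `[0, 2*pi)`.
#' @param forest_gradient Logical; if `TRUE` forest cover increases from
#'   south to north so that the landscape has a spatial gradient, if `FALSE`
#'   forest cover is spatially unstructured.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_sites = 6, n_species = 10, seed = 1)
#' @export
sim_config <- function(n_sites = 24L,
                       n_stations = 3L,
                       n_periods = 52L,
                       periods_per_year = 26L,
                       n_species = 40L,
                       seed = 1L,
                       seasonal_gain = 1.5,
                       trend_sd = 0.004,
                       dispersion = 2,
                       status_probs = c(native = 0.5, alien = 0.2,
                                        uncertain = 0.3),
                       baseline_log_mean = log(3),
                       baseline_log_sd = 0.7,
                       amplitude_log_mean = log(0.6),
                       amplitude_log_sd = 0.3,
                       habitat_match = 0,
                       phase_kappa = 8,
                       forest_gradient = TRUE) {
  counts <- c(n_sites = n_sites, n_stations = n_stations,
              n_periods = n_periods, periods_per_year = periods_per_year,
              n_species = n_species)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("configuration error: counts must be integers >= 1", call. = FALSE)
  if (n_periods %% periods_per_year != 0)
    stop("configuration error: n_periods must be a multiple of periods_per_year",
         call. = FALSE)
  if (length(status_probs) != 3L ||
      !setequal(names(status_probs), c("native", "alien", "uncertain")))
    stop("configuration error: status_probs must be named over native/alien/uncertain",
         call. = FALSE)
  if (any(status_probs < 0) || abs(sum(status_probs) - 1) > 1e-8)
    stop("configuration error: status_probs must be non-negative and sum to 1",
         call. = FALSE)
  if (dispersion <= 0)
    stop("configuration error: dispersion must be positive (Inf = Poisson)",
         call. = FALSE)
  cfg <- list(n_sites = as.integer(n_sites),
              n_stations = as.integer(n_stations),
              n_periods = as.integer(n_periods),
              periods_per_year = as.integer(periods_per_year),
              n_species = as.integer(n_species),
              seed = as.integer(seed),
              seasonal_gain = seasonal_gain,
              trend_sd = trend_sd,
              dispersion = dispersion,
              status_probs = status_probs[c("native", "alien", "uncertain")],
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              amplitude_log_mean = amplitude_log_mean,
              amplitude_log_sd = amplitude_log_sd,
              habitat_match = habitat_match,
              phase_kappa = phase_kappa,
              forest_gradient = isTRUE(forest_gradient))
  class(cfg) <- "sim_config"
  cfg
}

land_classes <- c("forest", "agriculture", "urban", "grass", "sand",
                  "freshwater", "misc")

site_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Generate a synthetic landscape of monitoring sites
#'
#' Produces per-site projected coordinates (metres) and proportions of the
#' seven land-cover classes (forest, agriculture, urban, grass, sand,
#' freshwater, miscellaneous). Forest proportions span the full gradient from
#' near-complete development to near-complete forest; the non-forest share is
#' split so that developed classes (urban, agriculture) dominate where forest
#' is scarce. When `cfg$forest_gradient` is `TRUE` the forest proportion
#' increases with the y (northing) coordinate, mimicking a south-to-north
#' development gradient.
#'
#' @param cfg A [sim_config()] object.
#' @return A `data.frame` with columns `site`, `x`, `y` and the seven
#'   land-cover proportion columns (each row sums to 1).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  # deterministic spread guarantees the gradient span; jitter decorrelates
  base <- if (n == 1) 0.5 else seq(0.05, 0.95, length.out = n)
  forest <- pmin(0.97, pmax(0.03, base + stats::rnorm(n, 0, 0.02)))
  rest <- 1 - forest
  # developed classes take a larger share of the remainder where forest is low
  alpha <- cbind(agriculture = 3 * (1 - forest) + 0.5,
                 urban = 4 * (1 - forest) + 0.5,
                 grass = 1.5,
                 sand = 0.4,
                 freshwater = 0.4,
                 misc = 0.4)
  g <- matrix(stats::rgamma(n * 6, shape = as.vector(alpha)), nrow = n)
  g <- g / rowSums(g)
  props <- cbind(forest = forest, g * rest)
  colnames(props) <- land_classes
  extent <- 100000  # ~100 km transect, projected metres
  x <- stats::runif(n, 0, extent / 3)
  if (cfg$forest_gradient) {
    # northing follows the forest rank, with scatter
    y <- extent * (rank(forest, ties.method = "first") - 0.5) / n +
      stats::rnorm(n, 0, extent / (4 * n))
  } else {
    y <- stats::runif(n, 0, extent)
  }
  data.frame(site = site_ids(n), x = x, y = y, props,
             stringsAsFactors = FALSE)
}

# Best-Fisher rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Generate a species pool with ground-truth dynamics
#'
#' Draws a species status table (native / alien / uncertain), a habitat
#' affinity per species, and the ground-truth parameters of every
#' species-by-site activity series: baseline log rate, seasonal amplitude `A`
#' on the log scale, peak phase `phi`, and a per-period trend slope.
#'
#' The log amplitude of species `s` at site `i` is
#' `log A0_s + seasonal_gain * (forest_i - 0.5)`, so with positive
#' `seasonal_gain` every species is more seasonal where forest cover is high,
#' while `seasonal_gain = 0` severs the link entirely. Phases are drawn from
#' a von Mises distribution concentrated on a common annual peak for
#' forest-affiliated species and uniformly for developed-affiliated species,
#' so that phase coherence (synchrony) differs by habitat affiliation.
#' Affinity probabilities depend on status (aliens and uncertain species tend
#' to be developed-affiliated), which makes status-level synchrony contrasts
#' reproducible as a scenario rather than being hard-coded.
#'
#' @param cfg A [sim_config()] object.
#' @param meta Landscape table from [generate_landscape()].
#' @return A list with `species` (data.frame: `species`, `status`,
#'   `affinity`) and `truth` (data.frame keyed by `species` x `site` with
#'   `baseline`, `amplitude`, `phase`, `slope`, `forest`).
#' @export
generate_species_pool <- function(cfg, meta) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(c("site", "forest") %in% names(meta)))
    stop("key error: meta must carry site and forest columns", call. = FALSE)
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_species
  sp <- sprintf("sp%03d", seq_len(ns))
  status <- sample(names(cfg$status_probs), ns, replace = TRUE,
                   prob = cfg$status_probs)
  p_forest_affine <- c(native = 0.8, alien = 0.15, uncertain = 0.4)
  affinity <- ifelse(stats::runif(ns) < p_forest_affine[status],
                     "forest", "developed")
  baseline0 <- stats::rnorm(ns, cfg$baseline_log_mean, cfg$baseline_log_sd)
  log_amp0 <- stats::rnorm(ns, cfg$amplitude_log_mean, cfg$amplitude_log_sd)
  phase <- numeric(ns)
  fa <- affinity == "forest"
  peak <- pi / 2  # common annual activity peak
  if (any(fa)) phase[fa] <- rvonmises(sum(fa), peak, cfg$phase_kappa)
  if (any(!fa)) phase[!fa] <- stats::runif(sum(!fa), 0, 2 * pi)

  grid <- expand.grid(species = sp, site = meta$site,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx_sp <- match(grid$species, sp)
  forest <- meta$forest[match(grid$site, meta$site)]
  match_term <- cfg$habitat_match *
    ifelse(affinity[idx_sp] == "forest", forest - 0.5, 0.5 - forest)
  truth <- data.frame(
    species = grid$species,
    site = grid$site,
    baseline = baseline0[idx_sp] + match_term,
    amplitude = exp(log_amp0[idx_sp] + cfg$seasonal_gain * (forest - 0.5)),
    phase = phase[idx_sp],
    slope = stats::rnorm(nrow(grid), 0, cfg$trend_sd),
    forest = forest,
    stringsAsFactors = FALSE)
  list(species = data.frame(species = sp, status = status,
                            affinity = affinity, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate station-level trap counts
#'
#' Draws the activity table. For every species x site x period, the site-level
#' count is negative binomial with log mean
#' `baseline + A * sin(2*pi*t/m + phi) + slope * t` (`m` periods per year)
#' and size parameter `cfg$dispersion` (`Inf` = Poisson). The site-level count
#' is then split across the site's stations by a multinomial draw with fixed
#' per-site station weights, so that summing stations recovers the site count
#' exactly.
#'
#' @param meta Landscape table from [generate_landscape()].
#' @param pool Species pool from [generate_species_pool()].
#' @param cfg A [sim_config()] object.
#' @return A long-format `data.frame` (`site`, `station`, `species`,
#'   `period`, `count`) with non-negative integer counts.
#' @export
simulate_counts <- function(meta, pool, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- pool$truth
  if (!setequal(unique(truth$site), meta$site))
    stop("key error: truth and meta disagree on site ids", call. = FALSE)
  set.seed(cfg$seed + 2L)
  m <- cfg$periods_per_year
  t_idx <- seq_len(cfg$n_periods)
  nst <- cfg$n_stations
  # fixed per-site station weights (Dirichlet(5)); station effect only
  w <- matrix(stats::rgamma(cfg$n_sites * nst, shape = 5),
              nrow = cfg$n_sites)
  w <- w / rowSums(w)
  rownames(w) <- meta$site

  nr <- nrow(truth)
  # log-mean matrix: rows = species x site, cols = periods
  ang <- outer(truth$phase, rep(1, length(t_idx))) +
    matrix(2 * pi * t_idx / m, nrow = nr, ncol = length(t_idx), byrow = TRUE)
  mu <- exp(truth$baseline + outer(truth$slope, t_idx) +
              truth$amplitude * sin(ang))
  ncell <- length(mu)
  if (is.infinite(cfg$dispersion)) {
    site_counts <- stats::rpois(ncell, lambda = as.vector(mu))
  } else {
    site_counts <- stats::rnbinom(ncell, mu = as.vector(mu),
                                  size = cfg$dispersion)
  }
  site_counts <- matrix(site_counts, nrow = nr)

  # multinomial station split of each site-level count
  wrow <- w[truth$site, , drop = FALSE]
  out <- vector("list", nst)
  remaining <- site_counts
  prob_left <- rep(1, nr)
  for (j in seq_len(nst - 1L)) {
    pj <- wrow[, j] / prob_left
    pj[!is.finite(pj)] <- 0
    pj <- pmin(pmax(pj, 0), 1)
    draw <- matrix(stats::rbinom(ncell, size = as.vector(remaining),
                                 prob = rep(pj, ncol(remaining))),
                   nrow = nr)
    out[[j]] <- draw
    remaining <- remaining - draw
    prob_left <- prob_left - wrow[, j]
  }
  out[[nst]] <- remaining

  tab <- do.call(rbind, lapply(seq_len(nst), function(j) {
    data.frame(site = rep(truth$site, times = length(t_idx)),
               station = j,
               species = rep(truth$species, times = length(t_idx)),
               period = rep(t_idx, each = nr),
               count = as.vector(out[[j]]),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$site, tab$station, tab$species, tab$period), ]
  rownames(tab) <- NULL
  tab
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper running [generate_landscape()],
#' [generate_species_pool()] and [simulate_counts()] for one configuration.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `meta`, `species`, `truth`, `counts` and `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  meta <- generate_landscape(cfg)
  pool <- generate_species_pool(cfg, meta)
  counts <- simulate_counts(meta, pool, cfg)
  list(meta = meta, species = pool$species, truth = pool$truth,
       counts = counts, cfg = cfg)
}

#' Write a simulated data set to CSV files
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meta = file.path(dir, "site_metadata.csv"),
             species = file.path(dir, "species_status.csv"),
             truth = file.path(dir, "ground_truth.csv"),
             counts = file.path(dir, "activity.csv"),
             config = file.path(dir, "config.txt"))
  utils::write.csv(sim$meta, paths["meta"], row.names = FALSE)
  utils::write.csv(sim$species, paths["species"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(sim$counts, paths["counts"], row.names = FALSE)
  write_config(sim$cfg, paths["config"])
  invisible(paths)
}

#' Write a configuration as flat key: value text
#' @param cfg A [sim_config()] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  flat <- unlist(cfg)
  writeLines(paste0(names(flat), ": ", format(flat, digits = 15,
                                              trim = TRUE)), path)
  invisible(path)
}
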